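# Independent oracles used to cross-check the package implementations.
# Each is written from the rule definitions directly, sharing no code with
# the implementation it checks.

# --- degradome category rule evaluator ---------------------------------
# Evaluates every category predicate independently and asserts that exactly
# one fires (the partition property), then returns it.
oracleCategory <- function(profile, site, window = 1L) {
    lo <- max(1L, site - window)
    hi <- min(length(profile), site + window)
    a <- max(profile[lo:hi])
    mx <- max(profile)
    med <- if (sum(profile >= 1) > 0) median(profile[profile >= 1]) else NA
    nAtMax <- length(which(profile == mx))
    cats <- character(0)
    if (a == 0) cats <- c(cats, "unsupported")
    if (a > 0 && a == mx && nAtMax == 1) cats <- c(cats, "0")
    if (a > 0 && a == mx && nAtMax > 1) cats <- c(cats, "1")
    if (a > 1 && a < mx && a > med) cats <- c(cats, "2")
    if (a > 1 && a < mx && a <= med) cats <- c(cats, "3")
    if (a == 1 && a < mx) cats <- c(cats, "4")
    stopifnot(length(cats) == 1L)
    cats
}

# --- plant duplex-penalty enumerator -----------------------------------
# Enumerates every admissible alignment (ungapped, one bulged target nt at
# any gap position, one bulged miRNA nt at any position) and returns the
# minimum penalty.  Penalties: WC 0, G:U 0.5, mismatch 1, bulged nt 1;
# doubled at miRNA positions 2-13.
.oraclePen <- local({
    b <- c("A", "C", "G", "T")
    m <- matrix(1, 4, 4, dimnames = list(b, b))
    m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 0
    m["G", "T"] <- m["T", "G"] <- 0.5
    m
})

oracleDuplexScore <- function(mir, win) {
    M <- nchar(mir); W <- nchar(win)
    mv <- strsplit(mir, "")[[1]]
    wv <- strsplit(win, "")[[1]]
    wt <- ifelse(seq_len(M) >= 2 & seq_len(M) <= 13, 2, 1)
    wtOf <- function(i) if (i >= 2 && i <= 13) 2 else 1
    score <- function(i, t) sum(.oraclePen[cbind(mv[i], wv[t])] * wt[i])
    best <- Inf
    if (W == M)
        best <- min(best, score(1:M, W + 1 - (1:M)))
    if (W == M + 1) {
        for (b in 0:M) {
            i <- 1:M
            t <- ifelse(i <= b, W + 1 - i, W - i)
            best <- min(best, score(i, t) + wtOf(b + 1))
        }
    }
    if (W == M - 1) {
        for (b in 1:M) {
            i <- setdiff(1:M, b)
            t <- ifelse(i < b, W + 1 - i, W + 2 - i)
            best <- min(best, score(i, t) + wtOf(b))
        }
    }
    best
}

# minimum duplex penalty of a miRNA anywhere inside a longer window
oracleBestInWindow <- function(mir, win) {
    M <- nchar(mir); L <- nchar(win)
    best <- Inf
    for (W in (M - 1):(M + 1)) {
        if (W < 1 || W > L) next
        for (s in 1:(L - W + 1))
            best <- min(best,
                        oracleDuplexScore(mir, substr(win, s, s + W - 1)))
    }
    best
}

# --- exhaustive nested-structure enumerator (tiny sequences) ------------
# Maximum number of nested base pairs with minimum loop size, by brute
# force recursion.  Only feasible for short sequences.
oracleMaxPairs <- function(seq, minLoop = 3L) {
    v <- strsplit(seq, "")[[1]]
    canPair <- function(a, b)
        (a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G") ||
        (a == "G" && b == "T") || (a == "T" && b == "G")
    rec <- function(i, j) {
        if (j - i < minLoop + 1L) return(0L)
        best <- rec(i, j - 1L)
        for (k in i:(j - minLoop - 1L)) {
            if (canPair(v[k], v[j])) {
                left <- if (k > i) rec(i, k - 1L) else 0L
                mid <- if (j - k - 1L > 0) rec(k + 1L, j - 1L) else 0L
                best <- max(best, left + 1L + mid)
            }
        }
        best
    }
    rec(1L, length(v))
}

# --- hand-written promoter rule table ----------------------------------
# orientation: "same" / "opposite" / "none"; gap: intergenic bp.
# Returns the expected branch and promoter length (NA length when the
# default branch would be clipped; callers avoid that geometry).
oraclePromoterRule <- function(orientation, gap) {
    if (orientation == "same" && !is.na(gap) && gap < 2400) {
        if (gap <= 400) return(list(branch = "default_2kb", length = 2000))
        return(list(branch = "same_dir_near", length = gap - 400))
    }
    if (orientation == "opposite" && !is.na(gap) && gap > 4000)
        return(list(branch = "opposite_far", length = gap %/% 2))
    list(branch = "default_2kb", length = 2000)
}

# --- exact hypergeometric tail by combinatorial arithmetic --------------
oracleHyperP <- function(k, K, n, N) {
    i <- k:min(K, n)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- misc ---------------------------------------------------------------
oracleRevcomp <- function(x) {
    vapply(x, function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s),
                                             "")[[1]]), collapse = ""), "",
           USE.NAMES = FALSE)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
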