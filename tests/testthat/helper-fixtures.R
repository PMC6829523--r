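# Shared fixtures, built once per test run and cached.
#
# smallConfig(): a reduced fixture for unit tests (12 known + 3 novel loci,
# 8k reads/library) keeping the full study layout (3 conditions x 3
# replicates, 4 repressed miRNAs at 4-fold, NB dispersion 0.1).
#
# studyConfig(): the reference study conditions (50 known + 8 novel loci,
# 1e5 reads/library) with Poisson counts -- the sampling model of the DE
# test -- used for the end-to-end parameter-recovery checks.

.fixCache <- new.env(parent = emptyenv())

smallConfig <- function(seed = 101L) {
    simConfig(seed = seed, genomeLength = 1.5e5, nKnownMirnas = 12L,
              nNovelMirnas = 3L, nTranscripts = 20L,
              depthPerLibrary = 8000)
}

studyConfig <- function(seed = 1L) {
    simConfig(seed = seed, dispersion = 0)
}

smallFixture <- function() {
    if (is.null(.fixCache$fx)) .fixCache$fx <- makeGenome(smallConfig())
    .fixCache$fx
}

smallFixtureDir <- function() {
    if (is.null(.fixCache$dir)) {
        d <- file.path(tempdir(), "mirisr-fixture-small")
        if (!file.exists(file.path(d, "manifest.yaml")))
            writeFixture(smallConfig(), d, fixture = smallFixture())
        .fixCache$dir <- d
    }
    .fixCache$dir
}

# one full pipeline run on the small fixture; returns the output directory
smallRunDir <- function() {
    if (is.null(.fixCache$run)) {
        d <- file.path(tempdir(), "mirisr-run-small")
        conf <- pipelineConfigFromFixture(smallFixtureDir(), d, seed = 101L)
        suppressMessages(runPipeline(conf))
        .fixCache$run <- d
    }
    .fixCache$run
}

# one full pipeline run under the reference study conditions
studyRun <- function() {
    if (is.null(.fixCache$study)) {
        fd <- file.path(tempdir(), "mirisr-fixture-study")
        rd <- file.path(tempdir(), "mirisr-run-study")
        cfg <- studyConfig()
        if (!file.exists(file.path(fd, "manifest.yaml")))
            writeFixture(cfg, fd)
        conf <- pipelineConfigFromFixture(fd, rd, seed = 1L)
        suppressMessages(runPipeline(conf))
        .fixCache$study <- list(config = cfg, fixtureDir = fd, runDir = rd,
                                truth = read.delim(file.path(fd,
                                                             "truth.tsv")))
    }
    .fixCache$study
}

readRun <- function(dir, file, ...) read.delim(file.path(dir, file), ...)
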