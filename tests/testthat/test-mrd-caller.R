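mkModel <- function(depth = 30000L) {
    handPileup("ACGT", list(stats::setNames(depth, "A"),
                            stats::setNames(depth, "C"),
                            stats::setNames(depth, "G"),
                            stats::setNames(depth, "T"))) |>
        list() |> fitErrorModel()
}

test_that("zero alternate support is not-detected with VAF 0", {
    pl <- handPileup("ACGT", list(c(A = 10000L), c(C = 10000L),
                                  c(G = 10000L), c(T = 10000L)))
    tr <- trackedMutations("P1", "NRAS", "T1", 2, "C", "A", 0.4)
    calls <- callTrackedMutations(pl, tr, mkModel())
    expect_identical(calls$status, "not-detected")
    expect_identical(calls$vaf, 0)
    expect_identical(calls$altFamilies, 0L)
})

test_that("a 0.5% spike is detected with an accurate VAF estimate", {
    ref <- randomRef(40, seed = 20)
    sp <- spikeAlleles(ref)
    ctrl <- lapply(1:2, function(i)
        consensusPileup(simulateSample(simConfig(c(T1 = ref), 11600,
                                                 seed = 600 + i))))
    m <- fitErrorModel(ctrl)
    s <- simulateSample(snvSpikeConfig(ref, 11600, 0.005, seed = 61))
    pl <- consensusPileup(s)
    tr <- trackedMutations("P1", "NRAS", "T1", sp$pos, sp$ref, sp$alt, 0.4)
    calls <- callTrackedMutations(pl, tr, m)
    expect_identical(calls$status, "detected")
    se <- sqrt(0.005 * 0.995 / calls$consensusDepth)
    expect_lt(abs(calls$vaf - 0.005), 3 * se)
    expect_lt(calls$qValue, 1e-6)
})

test_that("an NPM1-type 4-bp insertion at 0.03% is detected in most replicates", {
    ref <- randomRef(40, seed = 21)
    pos <- 20L
    rb <- substr(ref, pos, pos)
    insAlt <- paste0(rb, substr(ref, pos - 3L, pos))
    ctrl <- lapply(1:3, function(i)
        consensusPileup(simulateSample(simConfig(c(T1 = ref), 43842,
                                                 seed = 700 + i))))
    m <- fitErrorModel(ctrl)
    tr <- trackedMutations("P2", "NPM1", "T1", pos, rb, insAlt, 0.4)
    det <- vapply(1:20, function(i) {
        cfg <- simConfig(c(T1 = ref), 43842, seed = 800 + i,
                         spikeIns = data.frame(target = "T1", pos = pos,
                                               ref = rb, alt = insAlt,
                                               vaf = 3e-4, id = "npm1"))
        suppressMessages({
            pl <- consensusPileup(simulateSample(cfg))
        })
        calls <- callTrackedMutations(pl, tr, m)
        calls$status[1] == "detected"
    }, logical(1))
    expect_gte(mean(det), 0.5)
})

test_that("missing sites, low depth and unmodeled sites are untestable", {
    pl <- handPileup("ACGT", list(c(A = 500L), c(C = 500L), c(G = 500L),
                                  c(T = 500L)))
    m <- mkModel()
    trLow <- trackedMutations("P1", "KIT", "T1", 2, "C", "A", 0.3)
    c1 <- callTrackedMutations(pl, trLow, m)
    expect_identical(c1$status, "untestable")
    expect_match(c1$reason, "depth")

    trMissing <- trackedMutations("P1", "KIT", "T9", 2, "C", "A", 0.3)
    c2 <- callTrackedMutations(pl, trMissing, m)
    expect_identical(c2$status, "untestable")
    expect_match(c2$reason, "absent")

    plDeep <- handPileup("ACGT", list(c(A = 5000L), c(C = 5000L),
                                      c(G = 5000L), c(T = 5000L)))
    mZero <- fitErrorModel(list(handPileup("ACGT", list(
        c(A = 1000L), c(C = 0L), c(G = 1000L), c(T = 1000L)))))
    c3 <- callTrackedMutations(plDeep, trLow, mZero)
    expect_identical(c3$status, "untestable")
    expect_match(c3$reason, "unmodeled")

    itd <- trackedMutations("P1", "FLT3", "T1", 2, "C", "C", 0.3,
                            class = "ITD")
    c4 <- callTrackedMutations(plDeep, itd, m)
    expect_identical(c4$status, "untestable")
})

detCalls <- function(genes, statuses) {
    tr <- trackedMutations("P7", genes, "T1", seq_along(genes) + 1L,
                           "C", "A", 0.3)
    tr$altFamilies <- 10L; tr$consensusDepth <- 10000L
    tr$vaf <- 1e-3; tr$pValue <- 1e-9; tr$qValue <- 1e-9
    tr$status <- statuses
    tr$reason <- NA_character_
    tr
}

test_that("the DTA policy separates clonal hematopoiesis from residual disease", {
    # PC: a sole persistent TET2 clone never makes the sample positive
    tet2 <- detCalls("TET2", "detected")
    expect_identical(mrdStatus(classifySample(tet2, timePoint = "PC")),
                     "MRD-negative")
    # PI under the permissive policy: the same clone counts
    expect_identical(mrdStatus(classifySample(tet2, timePoint = "PI")),
                     "MRD-positive")
    expect_identical(mrdStatus(classifySample(tet2, timePoint = "PI",
                                              dtaPolicy = "strict")),
                     "MRD-negative")
    # a detected non-DTA mutation is positive regardless of policy/time
    nras <- detCalls(c("TET2", "NRAS"), c("detected", "detected"))
    for (tp in c("PI", "PC"))
        expect_identical(mrdStatus(classifySample(nras, timePoint = tp,
                                                  dtaPolicy = "strict")),
                         "MRD-positive")
    expect_identical(mrdBasis(classifySample(nras, timePoint = "PC"))[1],
                     nras$id[2])
    # flipping isDta on the sole detected mutation flips PC classification
    fake <- detCalls("NRAS", "detected")
    expect_identical(mrdStatus(classifySample(fake, timePoint = "PC")),
                     "MRD-positive")
    flipped <- fake
    flipped$isDta <- TRUE
    expect_identical(mrdStatus(classifySample(flipped, timePoint = "PC")),
                     "MRD-negative")
    # no testable calls: untestable, not negative
    none <- detCalls("NRAS", "untestable")
    expect_identical(mrdStatus(classifySample(none, timePoint = "PC")),
                     "untestable")
    expect_identical(mrdStatus(classifySample(detCalls("NRAS",
                                                       "detected")[0, ])),
                     "untestable")
})

test_that("MRD kinetics categorize time-point pairs and list gains/losses", {
    two <- detCalls(c("NRAS", "IDH1"), c("detected", "detected"))
    one <- detCalls(c("NRAS", "IDH1"), c("detected", "not-detected"))
    neither <- detCalls(c("NRAS", "IDH1"),
                        c("not-detected", "not-detected"))
    pi <- classifySample(two, timePoint = "PI")
    pc <- classifySample(one, timePoint = "PC")
    k <- mrdKinetics(pi, pc)
    expect_identical(k$category, "pos/pos")
    expect_identical(k$lost, two$id[2])
    expect_length(k$gained, 0)

    k2 <- mrdKinetics(classifySample(one, timePoint = "PI"),
                      classifySample(neither, timePoint = "PC"))
    expect_identical(k2$category, "pos->neg")
    expect_identical(k2$lost, one$id[1])

    k3 <- mrdKinetics(classifySample(neither, timePoint = "PI"),
                      classifySample(one, timePoint = "PC"))
    expect_identical(k3$category, "neg->pos")
    expect_identical(k3$gained, one$id[1])

    k4 <- mrdKinetics(classifySample(neither, timePoint = "PI"),
                      classifySample(neither, timePoint = "PC"))
    expect_identical(k4$category, "neg/neg")
    expect_false(k4$changed)

    other <- detCalls("NRAS", "detected")
    other$patient <- "P8"
    expect_error(mrdKinetics(pi, classifySample(other, patient = "P8",
                                                timePoint = "PC")),
                 "different patients")
})

test_that("error-only samples stay MRD-negative at the expected rate", {
    ref <- randomRef(40, seed = 22)
    mk <- function(seed)
        consensusPileup(simulateSample(simConfig(c(T1 = ref), 8000,
                                                 seed = seed)))
    m <- fitErrorModel(lapply(1:3, function(i) mk(1200 + i)))
    alleles <- lapply(c(10L, 20L, 30L), function(p)
        list(pos = p, ref = substr(ref, p, p),
             alt = setdiff(c("A", "C", "G", "T"), substr(ref, p, p))[1]))
    tr <- trackedMutations("P9", c("NRAS", "IDH2", "KIT"), "T1",
                           vapply(alleles, `[[`, 0L, "pos"),
                           vapply(alleles, `[[`, "", "ref"),
                           vapply(alleles, `[[`, "", "alt"),
                           rep(0.3, 3))
    th <- mrdThresholds(minDepth = 1000L)
    pos <- vapply(1:60, function(i) {
        calls <- callTrackedMutations(mk(1300 + i), tr, m, th)
        mrdStatus(classifySample(calls, timePoint = "PC")) == "MRD-positive"
    }, logical(1))
    bound <- 0.05 * 3 + 3 * sqrt(0.15 * 0.85 / 60)
    expect_lte(mean(pos), bound)
})

test_that("detection rate is non-decreasing in spike VAF", {
    tab <- lodExperiment(vafGrid = c(1e-4, 1e-3, 5e-3),
                         consensusDepth = 3000L, reps = 12, seed = 33)
    rates <- tab$rate
    se <- sqrt(pmax(rates * (1 - rates), 0.25 / 12) / 12)
    expect_true(all(diff(rates) >= -3 * (se[-1] + se[-length(se)])))
})
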