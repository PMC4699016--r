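test_that("global-motion removal undoes a rigid tumble and is idempotent", {
    set.seed(31)
    base <- makeIdealHelix(12)
    F <- 8
    coords <- array(NA_real_, c(12, 3, F))
    for (f in 1:F) {
        R <- rotationAboutAxis(rnorm(3), runif(1, 0, 180))
        coords[, , f] <- sweep(base %*% t(R), 2, rnorm(3), "+")
    }
    traj <- caTrajectory(coords, 50)
    ref <- caStructure(base)
    fit <- removeGlobalMotion(traj, ref)
    for (f in 1:F)
        expect_lt(max(abs(frameCoords(fit, f) - base)), 1e-9)
    fit2 <- removeGlobalMotion(fit, ref)
    expect_lt(max(abs(fit2@coords - fit@coords)), 1e-9)
})

test_that("removal preserves internal motion and leaves d(f) invariant", {
    # tumble + hinge: V static, W rolls; after removal the residual motion
    # equals the hinge-only ground truth
    sim <- generateTwoDomainTrajectory(
        motionSpec(sigmaNm = 0),
        motionSpec(angleType = "sinusoid", amplitudeDeg = 30,
                   periodFrames = 17, sigmaNm = 0),
        nFrames = 40, seed = 33)
    hinge <- sim$trajectory
    tumbled <- hinge
    set.seed(34)
    for (f in seq_len(nFrames(hinge))) {
        R <- rotationAboutAxis(rnorm(3), runif(1, 0, 180))
        tumbled@coords[, , f] <-
            sweep(hinge@coords[, , f] %*% t(R), 2, rnorm(3), "+")
    }
    ref <- caStructure(frameCoords(hinge, 1))
    selV <- sim$selV
    refit <- removeGlobalMotion(tumbled, ref, fitSelection = selV)
    for (f in seq_len(nFrames(hinge))) {
        rPost <- kabsch(frameCoords(refit, f, sim$selW),
                        frameCoords(hinge, f, sim$selW))$rmsd
        expect_lt(rPost, 1e-6)  # hinge motion survives (round-off only)
        dTumbled <- centerDistance(frameCoords(tumbled, f, selV),
                                   frameCoords(tumbled, f, sim$selW))
        dRefit <- centerDistance(frameCoords(refit, f, selV),
                                 frameCoords(refit, f, sim$selW))
        expect_equal(dTumbled, dRefit, tolerance = 1e-9)
    }
})

test_that("central-frame search matches brute force, ties and strides", {
    # all frames identical: profile is zero, tie broken to frame 1
    base <- makeIdealHelix(10)
    coords <- array(rep(base, 5), c(10, 3, 5))
    traj <- caTrajectory(coords, 50)
    sel <- resolveSelection("1-10", traj)
    expect_message(ref <- findCentralFrame(traj, sel), "tie")
    expect_equal(centralFrame(ref), 1L)
    expect_equal(ref@profile, rep(0, 5), tolerance = 1e-12)

    # frame 2's shape is midway between shapes 1 and 3 (a pure rigid
    # interpolation would superpose to zero RMSD everywhere)
    set.seed(36)
    defo <- matrix(rnorm(30, sd = 0.1), 10, 3)
    c3 <- array(NA_real_, c(10, 3, 3))
    for (f in 1:3)
        c3[, , f] <- (base + (f - 1) / 2 * defo) %*%
            t(rotationAboutAxis(c(1, 0, 0), c(0, 20, 40)[f]))
    tr3 <- caTrajectory(c3, 50)
    refc <- findCentralFrame(tr3, sel)
    expect_equal(centralFrame(refc), 2L)
    oracle <- bruteCentralFrame(tr3, sel)
    expect_equal(refc@profile, oracle$profile, tolerance = 1e-9)

    # stride equals brute force restricted to every stride-th frame
    sim <- generateCorrelatedRolling(0.5, nFrames = 40, seed = 35)
    tr <- sim$trajectory
    refS <- findCentralFrame(tr, sim$selV, stride = 10L)
    oracleS <- bruteCentralFrame(tr, sim$selV, stride = 10L)
    expect_equal(refS@profileFrames, as.integer(oracleS$frames))
    expect_equal(refS@profile, oracleS$profile, tolerance = 1e-9)
    expect_equal(centralFrame(refS), oracleS$k)
})

test_that("reference axes are deterministic, right-handed, helix-aligned", {
    sim <- generateTwoDomainTrajectory(motionSpec(sigmaNm = 0.02),
                                       motionSpec(sigmaNm = 0.02),
                                       nFrames = 30, seed = 37)
    ref1 <- buildReferenceAxes(sim$trajectory, sim$selV)
    ref2 <- buildReferenceAxes(sim$trajectory, sim$selV)
    expect_identical(axesMatrix(ref1), axesMatrix(ref2))
    expect_equal(det(axesMatrix(ref1)), 1, tolerance = 1e-9)
    # v1 near the helix z-axis
    expect_lt(acos(abs(axesMatrix(ref1)[3, 1])) * 180 / pi, 5)
    # minimal 3-atom non-collinear domain still yields a proper triad
    tri <- array(rep(rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0.4, 0.1)), 2),
                 c(3, 3, 2))
    trTri <- caTrajectory(tri, 50)
    refT <- buildReferenceAxes(trTri, resolveSelection("1-3", trTri))
    expect_equal(det(axesMatrix(refT)), 1, tolerance = 1e-9)
})

test_that("orientation series: rigid co-movement gives constant observables", {
    # W rigidly co-moving with V (same motion spec, same axis/profile)
    spec <- motionSpec(axis = c(0, 1, 1), angleType = "linear",
                       amplitudeDeg = 50, sigmaNm = 0)
    sim <- generateTwoDomainTrajectory(spec, spec, nFrames = 25, seed = 39)
    refV <- buildReferenceAxes(sim$trajectory, sim$selV)
    refW <- buildReferenceAxes(sim$trajectory, sim$selW)
    os <- computeOrientationSeries(sim$trajectory, refV, refW)
    expect_lt(max(apply(os@cosines, 2, function(x) diff(range(x)))), 1e-9)
    expect_lt(max(apply(os@euler, 2, function(x) diff(range(x)))), 1e-4)
    # transport identity residual per frame
    for (f in c(1, 13, 25))
        expect_lt(max(abs(os@triadsW[, , f] -
                          os@rotVW[, , f] %*% os@triadsV[, , f])), 1e-9)
})

test_that("identical domain against itself yields identity at every frame", {
    sim <- generateTwoDomainTrajectory(motionSpec(sigmaNm = 0.01),
                                       motionSpec(sigmaNm = 0.01),
                                       nFrames = 10, seed = 41)
    refV <- buildReferenceAxes(sim$trajectory, sim$selV)
    os <- computeOrientationSeries(sim$trajectory, refV, refV)
    expect_equal(os@cosines[centralFrame(refV), ], c(1, 1, 1),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_lt(max(abs(os@rotVW[, , centralFrame(refV)] - diag(3))), 1e-9)
    # self-comparison is exact at every frame, not just k
    expect_lt(max(abs(sweep(os@cosines, 2, c(1, 1, 1)))), 1e-9)
})

test_that("transported cosines evolve smoothly (no per-frame sign flips)", {
    # smooth roll: per-step cosine change is bounded by the angular step
    sim <- generateTwoDomainTrajectory(
        motionSpec(sigmaNm = 0.01),
        motionSpec(angleType = "sinusoid", amplitudeDeg = 60,
                   periodFrames = 80, sigmaNm = 0.01),
        nFrames = 160, seed = 43)
    refV <- buildReferenceAxes(sim$trajectory, sim$selV)
    refW <- buildReferenceAxes(sim$trajectory, sim$selW)
    os <- computeOrientationSeries(sim$trajectory, refV, refW)
    maxAngStep <- max(abs(diff(sim$truth$thetaW))) * pi / 180
    noiseTerm <- 0.15   # allowance for sigma = 0.01 nm coordinate noise
    for (j in 1:3)
        expect_lt(max(abs(diff(os@cosines[, j]))), maxAngStep + noiseTerm)
})

test_that("series TSV round-trips at 6 decimals with the documented header", {
    sim <- generateTwoDomainTrajectory(motionSpec(sigmaNm = 0.01),
                                       motionSpec(sigmaNm = 0.01),
                                       nFrames = 3, seed = 45)
    refV <- buildReferenceAxes(sim$trajectory, sim$selV)
    refW <- buildReferenceAxes(sim$trajectory, sim$selW)
    os <- computeOrientationSeries(sim$trajectory, refV, refW)
    p <- tempfile(fileext = ".tsv")
    writeSeries(os, p)
    lines <- readLines(p)
    expect_length(lines, 4L)
    expect_equal(strsplit(lines[1], "\t")[[1]],
                 c("frame", "time_ns", "d_nm", "cos1", "cos2", "cos3",
                   "alpha_deg", "beta_deg", "gamma_deg"))
    back <- readSeries(p)
    orig <- as.data.frame(os)
    for (cn in names(orig))
        expect_equal(back[[cn]], orig[[cn]], tolerance = 1e-6)
})
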