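## Synthetic ground-truth trajectories: two quasi-rigid C-alpha helices
## undergoing prescribed rigid-body motions with isotropic Gaussian
## deformation noise. Every pipeline stage is validated against the exact
## per-frame transforms these generators record.

#' Ideal alpha-helix C-alpha trace
#'
#' Standard helix along +z: rise 0.15 nm per residue, twist 100 degrees,
#' radius 0.23 nm, giving the canonical ~0.38 nm consecutive C-alpha
#' distance. The trace is returned centred at its geometric centre.
#'
#' @param nRes number of residues, >= 4.
#' @param riseNm rise per residue (nm).
#' @param twistDeg twist per residue (degrees).
#' @param radiusNm helix radius (nm).
#' @return numeric matrix (nRes x 3), nm.
#' @export
makeIdealHelix <- function(nRes, riseNm = 0.15, twistDeg = 100,
                           radiusNm = 0.23) {
    stopifnot(nRes >= 4)
    i <- seq_len(nRes) - 1
    phi <- i * twistDeg * pi / 180
    m <- cbind(radiusNm * cos(phi), radiusNm * sin(phi), i * riseNm)
    sweep(m, 2, colMeans(m))
}

#' Construct a motion specification
#'
#' @param axis rotation axis (normalised internally).
#' @param angleType `"constant"`, `"linear"`, `"sinusoid"` or `"series"`.
#' @param amplitudeDeg angle scale in degrees: the constant value, the
#'   total linear sweep, or the sinusoid amplitude.
#' @param periodFrames sinusoid period in frames.
#' @param angleSeries explicit per-frame angle series (degrees) for
#'   `angleType = "series"`.
#' @param driftNmPerFrame translation per frame (nm 3-vector).
#' @param sigmaNm isotropic Gaussian deformation noise sd per atom per
#'   frame (nm), default 0.02 -- a small fraction of the helix radius, so
#'   the domain stays quasi-rigid.
#' @return a [MotionSpec-class].
#' @export
motionSpec <- function(axis = c(0, 0, 1), angleType = "constant",
                       amplitudeDeg = 0, periodFrames = 100,
                       angleSeries = numeric(0),
                       driftNmPerFrame = c(0, 0, 0), sigmaNm = 0.02) {
    new("MotionSpec", axis = axis / sqrt(sum(axis^2)),
        angleType = angleType, amplitudeDeg = amplitudeDeg,
        periodFrames = periodFrames, angleSeries = angleSeries,
        driftNmPerFrame = driftNmPerFrame, sigmaNm = sigmaNm)
}

.angleProfile <- function(spec, F) {
    f <- seq_len(F) - 1
    switch(spec@angleType,
        constant = rep(spec@amplitudeDeg, F),
        linear = if (F == 1L) 0 else spec@amplitudeDeg * f / (F - 1),
        sinusoid = spec@amplitudeDeg * sin(2 * pi * f / spec@periodFrames),
        series = {
            if (length(spec@angleSeries) != F)
                stop("angleSeries length (", length(spec@angleSeries),
                     ") must equal the frame count (", F, ")")
            spec@angleSeries
        })
}

.syntheticAtoms <- function(nV, nW) {
    data.frame(eleno = seq_len(nV + nW), elety = "CA", resid = "ALA",
               chain = rep(c("A", "B"), c(nV, nW)),
               resno = c(seq_len(nV), seq_len(nW)),
               stringsAsFactors = FALSE)
}

#' Generate a two-domain trajectory with exact ground truth
#'
#' Two ideal helices (25 and 30 residues, the sizes of the two MHC
#' binding-groove helices) are placed `separationNm` apart along x with
#' parallel helix axes along z. The second helix is pre-rotated so that
#' its disambiguated PCA triad coincides with the first's ("axis
#' matched"), which makes prescribed relative rotations read off directly
#' from the recovered cosines. Per frame, each domain's rigid transform
#' (rotation about its own centre per its [MotionSpec-class], plus drift)
#' is applied, then i.i.d. isotropic Gaussian noise.
#'
#' The returned ground truth records, exactly and noise-free: the
#' per-frame rotation matrices, angle series, true transported triads
#' (rotation applied to the disambiguated base triad), true directional
#' cosines, Euler angles and centre distances.
#'
#' @param specV,specW [MotionSpec-class] for each domain.
#' @param separationNm initial centre-centre distance (nm).
#' @param nFrames number of frames.
#' @param timeStepPs time per frame (ps).
#' @param seed optional RNG seed for exact reproducibility.
#' @param nResV,nResW helix lengths in residues.
#' @return list with `trajectory` (a [CaTrajectory-class]), `selV`,
#'   `selW` ([DomainSelection-class]) and `truth` (list: thetaV, thetaW,
#'   rotV, rotW (3x3xF), triad0 (shared base [AxesTriad-class]),
#'   triadsV, triadsW (3x3xF true transported triads), cosines (F x 3),
#'   euler (F x 3), distance (F), centres).
#' @export
generateTwoDomainTrajectory <- function(specV, specW, separationNm = 3,
                                        nFrames = 500, timeStepPs = 500,
                                        seed = NULL, nResV = 25,
                                        nResW = 30) {
    stopifnot(is(specV, "MotionSpec"), is(specW, "MotionSpec"))
    if (!is.null(seed)) set.seed(seed)
    baseV <- makeIdealHelix(nResV)
    baseW <- makeIdealHelix(nResW)
    tri <- function(m) disambiguateAxes(pcaAxes(m), m)
    T0V <- tri(baseV)
    T0W <- tri(baseW)
    baseW <- baseW %*% t(axesMatrix(T0V) %*% t(axesMatrix(T0W)))
    # after matching, W's disambiguated triad equals V's
    ctrV <- c(0, 0, 0)
    ctrW <- c(separationNm, 0, 0)
    thetaV <- .angleProfile(specV, nFrames)
    thetaW <- .angleProfile(specW, nFrames)
    n <- nResV + nResW
    coords <- array(NA_real_, c(n, 3, nFrames))
    rotV <- array(NA_real_, c(3, 3, nFrames))
    rotW <- array(NA_real_, c(3, 3, nFrames))
    TVf <- array(NA_real_, c(3, 3, nFrames))
    TWf <- array(NA_real_, c(3, 3, nFrames))
    cosines <- matrix(NA_real_, nFrames, 3)
    euler <- matrix(NA_real_, nFrames, 3)
    dist <- numeric(nFrames)
    T0 <- axesMatrix(T0V)
    for (f in seq_len(nFrames)) {
        Rv <- rotationAboutAxis(specV@axis, thetaV[f])
        Rw <- rotationAboutAxis(specW@axis, thetaW[f])
        cv <- ctrV + (f - 1) * specV@driftNmPerFrame
        cw <- ctrW + (f - 1) * specW@driftNmPerFrame
        xv <- sweep(baseV %*% t(Rv), 2, cv, "+")
        xw <- sweep(baseW %*% t(Rw), 2, cw, "+")
        if (specV@sigmaNm > 0)
            xv <- xv + matrix(rnorm(3 * nResV, sd = specV@sigmaNm),
                              nResV, 3)
        if (specW@sigmaNm > 0)
            xw <- xw + matrix(rnorm(3 * nResW, sd = specW@sigmaNm),
                              nResW, 3)
        coords[, , f] <- rbind(xv, xw)
        rotV[, , f] <- Rv
        rotW[, , f] <- Rw
        Tv <- Rv %*% T0
        Tw <- Rw %*% T0
        TVf[, , f] <- Tv
        TWf[, , f] <- Tw
        cosines[f, ] <- directionCosines(Tv, Tw)
        euler[f, ] <- eulerXConvention(Tw %*% t(Tv))
        dist[f] <- sqrt(sum((cw - cv)^2))
    }
    traj <- caTrajectory(coords, timeStepPs,
                         atoms = .syntheticAtoms(nResV, nResW))
    list(trajectory = traj,
         selV = new("DomainSelection", name = "V",
                    indices = seq_len(nResV)),
         selW = new("DomainSelection", name = "W",
                    indices = as.integer(nResV + seq_len(nResW))),
         truth = list(thetaV = thetaV, thetaW = thetaW,
                      rotV = rotV, rotW = rotW, triad0 = T0V,
                      triadsV = TVf, triadsW = TWf, cosines = cosines,
                      euler = euler, distance = dist,
                      centres = rbind(V = ctrV, W = ctrW)))
}

#' Generate correlated "rolling" of two helices
#'
#' Both helices roll about their long (z) axes with zero-mean Gaussian
#' angle series drawn from a bivariate normal with correlation
#' `rhoTarget` and standard deviation `rollSdDeg`. An optional
#' moving-average window smooths both series (the filter preserves the
#' pair correlation but introduces serial dependence, which widens the
#' sampling distribution of the recovered correlation beyond the nominal
#' 1/sqrt(n-3); the default window of 1 keeps the draws independent so
#' that n frames carry n effective observations).
#'
#' @param rhoTarget target correlation, |rho| <= 1.
#' @param nFrames number of frames (default 503).
#' @param seed optional RNG seed.
#' @param sigmaNm deformation noise sd (nm), default 0.02.
#' @param rollSdDeg sd of the roll-angle series (degrees), default 20.
#' @param smoothWindow moving-average window in frames (default 1 = no
#'   smoothing).
#' @param separationNm centre-centre distance (nm).
#' @param timeStepPs time per frame (ps).
#' @return as [generateTwoDomainTrajectory()]; `truth$thetaV/W` hold the
#'   realised roll series.
#' @export
generateCorrelatedRolling <- function(rhoTarget, nFrames = 503,
                                      seed = NULL, sigmaNm = 0.02,
                                      rollSdDeg = 20, smoothWindow = 1,
                                      separationNm = 3, timeStepPs = 500) {
    stopifnot(abs(rhoTarget) <= 1)
    if (!is.null(seed)) set.seed(seed)
    z1 <- rnorm(nFrames)
    z2 <- rhoTarget * z1 + sqrt(1 - rhoTarget^2) * rnorm(nFrames)
    if (smoothWindow > 1) {
        k <- rep(1 / smoothWindow, smoothWindow)
        pad <- function(z) {
            zp <- c(rnorm(smoothWindow - 1), z)
            as.numeric(stats::filter(zp, k, sides = 1))[-seq_len(smoothWindow - 1)]
        }
        z1 <- pad(z1); z2 <- pad(z2)
        sc <- sqrt(smoothWindow)       # restore unit variance
        z1 <- z1 * sc; z2 <- z2 * sc
    }
    thV <- rollSdDeg * z1
    thW <- rollSdDeg * z2
    generateTwoDomainTrajectory(
        motionSpec(axis = c(0, 0, 1), angleType = "series",
                   angleSeries = thV, sigmaNm = sigmaNm),
        motionSpec(axis = c(0, 0, 1), angleType = "series",
                   angleSeries = thW, sigmaNm = sigmaNm),
        separationNm = separationNm, nFrames = nFrames,
        timeStepPs = timeStepPs)
}

#' Recover the roll-angle correlation of a two-helix trajectory
#'
#' Runs the full axis-transport machinery on each domain separately
#' (central-frame search, PCA triad, Kabsch transport) and correlates the
#' two recovered signed roll-angle series (see [rollAngleSeries()]).
#' Estimates the coupling the generator prescribed via `rhoTarget`.
#'
#' @param traj a [CaTrajectory-class].
#' @param selV,selW [DomainSelection-class] objects for the two domains.
#' @param stride central-frame search stride.
#' @param ciLevel confidence level for the Fisher-z interval.
#' @return list as [pearsonCorrelation()], plus `rollV`, `rollW` series.
#' @export
recoverRollCorrelation <- function(traj, selV, selW, stride = 1L,
                                   ciLevel = 0.95) {
    refV <- buildReferenceAxes(traj, selV, stride = stride)
    refW <- buildReferenceAxes(traj, selW, stride = stride)
    rollV <- rollAngleSeries(traj, refV)
    rollW <- rollAngleSeries(traj, refW)
    out <- pearsonCorrelation(rollV, rollW, ciLevel = ciLevel)
    out$rollV <- rollV
    out$rollW <- rollW
    out
}
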