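## Orchestration of the orientation analysis over a trajectory: global
## motion removal, central-frame search, reference-axis construction and
## per-frame axis transport by Kabsch rotations.

.domainCube <- function(traj, domain) {
    idx <- domainIndices(domain)
    if (max(idx) > caCount(traj))
        stop("selection '", domain@name, "' exceeds trajectory C-alpha ",
             "count (", caCount(traj), ")")
    traj@coords[idx, , , drop = FALSE]
}

#' Remove global translation and rotation from a trajectory
#'
#' Rigid-fits every frame onto a reference structure by Kabsch
#' superposition on a fit selection, i.e. removes translational and
#' rotational motion relative to the reference while preserving internal
#' deformations. Idempotent on an already-fitted trajectory.
#'
#' @param traj a [CaTrajectory-class].
#' @param reference a [CaStructure-class], or an N x 3 nm matrix of
#'   C-alpha coordinates matching the trajectory atom set.
#' @param fitSelection a [DomainSelection-class] naming the C-alpha atoms
#'   used for the fit (default: all).
#' @return the fitted [CaTrajectory-class].
#' @export
removeGlobalMotion <- function(traj, reference, fitSelection = NULL) {
    stopifnot(is(traj, "CaTrajectory"))
    refCa <- if (is(reference, "CaStructure")) caCoords(reference)
             else as.matrix(reference)
    if (nrow(refCa) != caCount(traj))
        stop("reference has ", nrow(refCa), " C-alpha atoms, trajectory ",
             "has ", caCount(traj))
    idx <- if (is.null(fitSelection)) seq_len(caCount(traj))
           else domainIndices(fitSelection)
    if (max(idx) > caCount(traj)) stop("fit selection out of bounds")
    refSel <- refCa[idx, , drop = FALSE]
    out <- traj@coords
    for (f in seq_len(nFrames(traj))) {
        fit <- kabsch(out[idx, , f], refSel)
        out[, , f] <- sweep(out[, , f] %*% t(fit$R), 2, fit$t, "+")
    }
    initialize(traj, coords = out)
}

#' Find the most central frame of a domain
#'
#' For each analysed frame i, the profile is the sum over analysed frames
#' j of the superposition-minimised RMSD between the domain at i and at
#' j; the central frame k is the argmin (ties resolved to the smallest
#' index, with a message). This is the anchor frame at which the PCA
#' triad is computed once. The search costs O(F^2) Kabsch fits; `stride`
#' restricts it to every stride-th frame.
#'
#' @param traj a [CaTrajectory-class].
#' @param domain a [DomainSelection-class].
#' @param stride positive integer; analyse frames `seq(1, F, stride)`.
#' @return a [ReferenceAxes-class] holding the central frame, its
#'   coordinates and the RMSD-sum profile; the triad slot is the identity
#'   placeholder until [buildReferenceAxes()] fills it.
#' @export
findCentralFrame <- function(traj, domain, stride = 1L) {
    stopifnot(is(traj, "CaTrajectory"), is(domain, "DomainSelection"),
              stride >= 1L)
    cube <- .domainCube(traj, domain)
    frames <- as.integer(seq.int(1L, nFrames(traj), by = stride))
    profile <- as.numeric(cpp_rmsd_profile(cube, frames - 1L))
    kpos <- which.min(profile)          # first minimum = smallest index
    if (sum(abs(profile - profile[kpos]) < 1e-12) > 1L)
        message("central-frame tie: choosing smallest frame index")
    k <- frames[kpos]
    new("ReferenceAxes", domain = domain, centralFrame = k,
        triad = new("AxesTriad", axes = diag(3),
                    eigenvalues = rep(NA_real_, 3)),
        coords = cube[, , which(frames == k)[1]],
        profile = profile, profileFrames = frames)
}

#' Build a domain's reference axes at its central frame
#'
#' Runs the central-frame search (unless `k` is given), performs the PCA
#' of the domain C-alpha coordinates at that frame, and fixes the axis
#' orientations against two in-domain atom pairs (see
#' [disambiguateAxes()]); the resulting triad is right-handed and is the
#' one transported to every frame by [computeOrientationSeries()].
#'
#' @param traj a [CaTrajectory-class].
#' @param domain a [DomainSelection-class].
#' @param k optional 1-based frame index to use as central frame; when
#'   omitted it is determined by [findCentralFrame()].
#' @param pair1,pair2 disambiguation atom pairs (in-domain indices);
#'   deterministic defaults when omitted.
#' @param stride stride for the central-frame search.
#' @return a [ReferenceAxes-class].
#' @export
buildReferenceAxes <- function(traj, domain, k = NULL, pair1 = NULL,
                               pair2 = NULL, stride = 1L) {
    if (is.null(k)) {
        ref <- findCentralFrame(traj, domain, stride = stride)
    } else {
        stopifnot(k >= 1L, k <= nFrames(traj))
        cube <- .domainCube(traj, domain)
        ref <- new("ReferenceAxes", domain = domain,
                   centralFrame = as.integer(k),
                   triad = new("AxesTriad", axes = diag(3),
                               eigenvalues = rep(NA_real_, 3)),
                   coords = cube[, , k],
                   profile = numeric(0), profileFrames = integer(0))
    }
    triad <- disambiguateAxes(pcaAxes(ref@coords), ref@coords,
                              pair1 = pair1, pair2 = pair2)
    initialize(ref, triad = triad)
}

#' Per-frame relative orientation of a domain pair
#'
#' For every analysed frame f, the domain's central-frame coordinates are
#' Kabsch-fitted onto the frame-f coordinates; the rotational part R(f)
#' transports the central-frame triad, T(f) = R(f) T(k). Doing this for
#' both domains gives R_VW(f) = T_W(f) T_V(f)^T, the directional cosines
#' v_i . w_i, the x-convention Euler angles and the centre distance d(f).
#' Because the triads are transported rather than recomputed, eigenvector
#' sign flips between frames cannot occur by construction.
#'
#' The orientation standardisation of W's reference axes against V's
#' (positive cosines v1.w1 and v2.w2) is applied once, to the reference
#' axes, never per frame.
#'
#' @param traj a [CaTrajectory-class].
#' @param refV,refW [ReferenceAxes-class] objects built from this
#'   trajectory (see [buildReferenceAxes()]).
#' @param applyAlignment flip W's reference axes to positive cosines
#'   against V's before transport (default TRUE).
#' @param frames integer vector of 1-based frames to analyse (default all).
#' @return an [OrientationSeries-class].
#' @export
computeOrientationSeries <- function(traj, refV, refW,
                                     applyAlignment = TRUE,
                                     frames = NULL) {
    stopifnot(is(traj, "CaTrajectory"),
              is(refV, "ReferenceAxes"), is(refW, "ReferenceAxes"))
    if (is.null(frames)) frames <- seq_len(nFrames(traj))
    frames <- as.integer(frames)
    if (any(frames < 1L | frames > nFrames(traj)))
        stop("frames out of range")
    cubeV <- .domainCube(traj, refV@domain)[, , frames, drop = FALSE]
    cubeW <- .domainCube(traj, refW@domain)[, , frames, drop = FALSE]
    TV0 <- axesMatrix(refV)
    TW0 <- if (applyAlignment)
        alignAxesToReference(refW@triad, refV@triad)@axes
    else axesMatrix(refW)

    fitV <- cpp_kabsch_series(refV@coords, cubeV)
    fitW <- cpp_kabsch_series(refW@coords, cubeW)
    F <- length(frames)
    cosines <- matrix(NA_real_, F, 3,
                      dimnames = list(NULL, c("cos1", "cos2", "cos3")))
    euler <- matrix(NA_real_, F, 3,
                    dimnames = list(NULL, c("alpha", "beta", "gamma")))
    d <- numeric(F)
    rotVW <- array(NA_real_, c(3, 3, F))
    TVf <- array(NA_real_, c(3, 3, F))
    TWf <- array(NA_real_, c(3, 3, F))
    for (i in seq_len(F)) {
        Tv <- fitV$rotations[, , i] %*% TV0
        Tw <- fitW$rotations[, , i] %*% TW0
        R <- Tw %*% t(Tv)
        if (max(abs(Tw - R %*% Tv)) > 1e-9)
            stop("internal error: transport residual exceeds 1e-9 at ",
                 "frame ", frames[i])
        TVf[, , i] <- Tv
        TWf[, , i] <- Tw
        rotVW[, , i] <- R
        cosines[i, ] <- directionCosines(Tv, Tw)
        euler[i, ] <- eulerXConvention(R)
        d[i] <- centerDistance(cubeV[, , i], cubeW[, , i])
    }
    new("OrientationSeries", frames = frames,
        timeNs = frames * timeStepPs(traj) / 1000,
        distance = d, cosines = cosines, euler = euler, rotVW = rotVW,
        triadsV = TVf, triadsW = TWf,
        domainV = refV@domain@name, domainW = refW@domain@name)
}

#' Signed roll angle of one domain about its own first axis
#'
#' Transports the domain's reference triad to every frame and reports the
#' signed angle (degrees) by which the transported second axis has
#' rotated about the reference first axis, relative to the central frame.
#' For a motion dominated by rotation about the major axis ("rolling",
#' e.g. an alpha-helix turning about its helical axis) this recovers the
#' roll angle series.
#'
#' @param traj a [CaTrajectory-class].
#' @param ref a [ReferenceAxes-class] for the domain.
#' @param frames frames to analyse (default all).
#' @return numeric vector of signed angles in degrees.
#' @export
rollAngleSeries <- function(traj, ref, frames = NULL) {
    stopifnot(is(traj, "CaTrajectory"), is(ref, "ReferenceAxes"))
    if (is.null(frames)) frames <- seq_len(nFrames(traj))
    cube <- .domainCube(traj, ref@domain)[, , frames, drop = FALSE]
    fit <- cpp_kabsch_series(ref@coords, cube)
    T0 <- axesMatrix(ref)
    v1 <- T0[, 1]; v2 <- T0[, 2]
    vapply(seq_along(frames), function(i) {
        w2 <- fit$rotations[, , i] %*% v2
        cross <- c(v2[2] * w2[3] - v2[3] * w2[2],
                   v2[3] * w2[1] - v2[1] * w2[3],
                   v2[1] * w2[2] - v2[2] * w2[1])
        atan2(sum(cross * v1), sum(v2 * w2)) * .RAD2DEG
    }, numeric(1))
}

#' Convert an orientation series to a data.frame
#'
#' @param x an [OrientationSeries-class].
#' @param ... unused.
#' @return data.frame with columns frame, time_ns, d_nm, cos1..cos3,
#'   alpha_deg, beta_deg, gamma_deg.
#' @export
setMethod("as.data.frame", "OrientationSeries", function(x, ...) {
    data.frame(frame = x@frames, time_ns = x@timeNs, d_nm = x@distance,
               cos1 = x@cosines[, 1], cos2 = x@cosines[, 2],
               cos3 = x@cosines[, 3],
               alpha_deg = x@euler[, 1], beta_deg = x@euler[, 2],
               gamma_deg = x@euler[, 3])
})

#' Write an orientation series as TSV
#'
#' Deterministic 6-decimal formatting; header
#' `frame time_ns d_nm cos1 cos2 cos3 alpha_deg beta_deg gamma_deg`.
#'
#' @param series an [OrientationSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSeries <- function(series, path) {
    df <- as.data.frame(series)
    for (cn in setdiff(names(df), "frame"))
        df[[cn]] <- sprintf("%.6f", df[[cn]])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an orientation-series TSV written by [writeSeries()]
#'
#' @param path TSV path.
#' @return data.frame (see [writeSeries()] for columns).
#' @export
readSeries <- function(path) {
    read.delim(path, check.names = FALSE)
}
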