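#' @import methods
#' @importFrom stats cor cor.test acf qnorm rnorm sd
#' @importFrom utils write.table read.delim head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib DomainOrient, .registration = TRUE
NULL

.isOrthonormal <- function(M, tol = 1e-9) {
    is.matrix(M) && all(dim(M) == c(3L, 3L)) &&
        max(abs(crossprod(M) - diag(3))) < tol
}

#' DomainSelection: a named set of C-alpha indices
#'
#' A domain is a set of 1-based C-alpha indices (possibly the union of
#' several sequence ranges, e.g. a beta-sheet) treated as a quasi-rigid
#' unit. Indices refer to the consecutive renumbering of C-alpha atoms
#' across the whole complex, in file chain order.
#'
#' @slot name single character label.
#' @slot indices sorted integer vector of distinct 1-based C-alpha indices.
#' @export
setClass("DomainSelection",
    representation(name = "character", indices = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
        if (length(object@indices) == 0L) msg <- c(msg, "selection is empty")
        if (any(object@indices < 1L)) msg <- c(msg, "indices must be >= 1")
        if (is.unsorted(object@indices, strictly = TRUE))
            msg <- c(msg, "indices must be strictly increasing")
        if (is.null(msg)) TRUE else msg
    })

#' CaStructure: a structure with renumbered C-alpha trace
#'
#' Atom records plus coordinates in nm. The C-alpha atoms, in file order
#' across all chains, carry a consecutive 1-based renumbering that is
#' independent of the PDB residue numbering; all domain selections refer
#' to these indices.
#'
#' @slot atoms data.frame with columns eleno, elety, resid, chain, resno.
#' @slot xyz numeric matrix (n_atoms x 3), coordinates in nm.
#' @slot caIdx integer vector: rows of `atoms` that are C-alpha atoms, in
#'   order; position i in this vector is C-alpha index i.
#' @export
setClass("CaStructure",
    representation(atoms = "data.frame", xyz = "matrix", caIdx = "integer"),
    validity = function(object) {
        msg <- NULL
        if (ncol(object@xyz) != 3L) msg <- c(msg, "xyz must have 3 columns")
        if (nrow(object@xyz) != nrow(object@atoms))
            msg <- c(msg, "atoms and xyz disagree in length")
        if (length(object@caIdx) &&
            (min(object@caIdx) < 1L || max(object@caIdx) > nrow(object@xyz)))
            msg <- c(msg, "caIdx out of range")
        if (is.null(msg)) TRUE else msg
    })

#' CaTrajectory: ordered coordinate frames for a fixed C-alpha set
#'
#' Only the C-alpha trace is retained: the analysis considers C-alpha
#' atoms exclusively. Frames are indexed 1-based; the time step is in ps
#' and is user-settable (trajectories are often subsampled, so the
#' effective time per frame need not equal the raw write-out interval).
#'
#' @slot coords numeric array (n_ca x 3 x n_frames), nm.
#' @slot timeStepPs positive number, time per frame in ps.
#' @slot atoms data.frame of the C-alpha atom records (one row per atom).
#' @export
setClass("CaTrajectory",
    representation(coords = "array", timeStepPs = "numeric",
                   atoms = "data.frame"),
    validity = function(object) {
        msg <- NULL
        d <- dim(object@coords)
        if (length(d) != 3L || d[2] != 3L)
            msg <- c(msg, "coords must be an n x 3 x F array")
        if (length(object@timeStepPs) != 1L || object@timeStepPs <= 0)
            msg <- c(msg, "timeStepPs must be a single positive number")
        if (is.null(msg)) TRUE else msg
    })

#' AxesTriad: a right-handable orthonormal axis triple
#'
#' Columns are the direction vectors v1, v2, v3 (descending eigenvalue
#' order when PCA-derived). Raw PCA output has arbitrary column signs;
#' after disambiguation v3 = v1 x v2 exactly, hence det = +1.
#'
#' @slot axes 3 x 3 numeric matrix, orthonormal columns.
#' @slot eigenvalues numeric(3), nm^2, non-increasing (NA if not from PCA).
#' @export
setClass("AxesTriad",
    representation(axes = "matrix", eigenvalues = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (!.isOrthonormal(object@axes, 1e-8))
            msg <- c(msg, "axes columns are not orthonormal")
        if (length(object@eigenvalues) != 3L)
            msg <- c(msg, "eigenvalues must have length 3")
        ev <- object@eigenvalues
        if (!anyNA(ev) && (any(ev < -1e-12) || is.unsorted(rev(ev))))
            msg <- c(msg, "eigenvalues must be non-negative and descending")
        if (is.null(msg)) TRUE else msg
    })

#' ReferenceAxes: a domain's body-fixed frame anchored at its central frame
#'
#' The central frame k minimises the summed pairwise superposition RMSD of
#' the domain to all other analysed frames; the PCA triad is computed once
#' there and transported elsewhere by Kabsch rotations.
#'
#' @slot domain the [DomainSelection-class] the axes belong to.
#' @slot centralFrame 1-based index of the central frame k.
#' @slot triad disambiguated [AxesTriad-class] at frame k.
#' @slot coords domain C-alpha coordinates at frame k (N x 3 nm, uncentred).
#' @slot profile RMSD-sum profile over the analysed frames (nm).
#' @slot profileFrames 1-based frame indices the profile was evaluated at.
#' @export
setClass("ReferenceAxes",
    representation(domain = "DomainSelection", centralFrame = "integer",
                   triad = "AxesTriad", coords = "matrix",
                   profile = "numeric", profileFrames = "integer"),
    validity = function(object) {
        msg <- NULL
        if (length(object@centralFrame) != 1L)
            msg <- c(msg, "centralFrame must be a single index")
        if (length(object@profile) != length(object@profileFrames))
            msg <- c(msg, "profile and profileFrames disagree in length")
        k <- match(object@centralFrame, object@profileFrames)
        if (length(object@profile) && (is.na(k) ||
            object@profile[k] > min(object@profile) + 1e-9))
            msg <- c(msg, "centralFrame does not minimise the profile")
        if (is.null(msg)) TRUE else msg
    })

#' OrientationSeries: per-frame relative orientation of a domain pair
#'
#' For every analysed frame f: the inter-domain centre distance d(f), the
#' transported triads T_V(f), T_W(f), the relative rotation
#' R_VW(f) = T_W(f) T_V(f)^T, the directional cosines v_i . w_i and the
#' x-convention Euler angles (degrees).
#'
#' @slot frames 1-based frame indices.
#' @slot timeNs time of each frame in ns.
#' @slot distance d(f) in nm.
#' @slot cosines F x 3 matrix of v_i . w_i.
#' @slot euler F x 3 matrix (alpha, beta, gamma), degrees, each in [0, 180].
#' @slot rotVW 3 x 3 x F array of relative rotations.
#' @slot triadsV,triadsW 3 x 3 x F arrays of transported triads.
#' @slot domainV,domainW domain names.
#' @export
setClass("OrientationSeries",
    representation(frames = "integer", timeNs = "numeric",
                   distance = "numeric", cosines = "matrix",
                   euler = "matrix", rotVW = "array",
                   triadsV = "array", triadsW = "array",
                   domainV = "character", domainW = "character"),
    validity = function(object) {
        F <- length(object@frames)
        ok <- length(object@timeNs) == F && length(object@distance) == F &&
            nrow(object@cosines) == F && nrow(object@euler) == F &&
            (F == 0L || dim(object@rotVW)[3] == F)
        if (ok) TRUE else "per-frame fields disagree in length"
    })

#' MotionSpec: a prescribed rigid-body motion with deformation noise
#'
#' Describes one domain's time-dependent rigid transform for the synthetic
#' generator: a rotation about a fixed axis through the domain centre with
#' a constant, linear, sinusoidal or explicitly given angle profile, a
#' linear drift, and isotropic Gaussian per-atom deformation noise.
#'
#' @slot axis unit 3-vector, rotation axis.
#' @slot angleType one of "constant", "linear", "sinusoid", "series".
#' @slot amplitudeDeg angle scale in degrees (constant value, total linear
#'   sweep, or sinusoid amplitude).
#' @slot periodFrames sinusoid period in frames.
#' @slot angleSeries explicit per-frame angles (deg) when angleType="series".
#' @slot driftNmPerFrame 3-vector translation per frame (nm).
#' @slot sigmaNm isotropic Gaussian deformation noise sd per atom (nm).
#' @export
setClass("MotionSpec",
    representation(axis = "numeric", angleType = "character",
                   amplitudeDeg = "numeric", periodFrames = "numeric",
                   angleSeries = "numeric", driftNmPerFrame = "numeric",
                   sigmaNm = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-9)
            msg <- c(msg, "axis must be a unit vector")
        if (!object@angleType %in% c("constant", "linear", "sinusoid",
                                     "series"))
            msg <- c(msg, "unknown angleType")
        if (object@sigmaNm < 0) msg <- c(msg, "sigmaNm must be >= 0")
        if (is.null(msg)) TRUE else msg
    })

## ---- accessors & show -----------------------------------------------------

#' @describeIn DomainSelection-class number of C-alpha atoms in the domain
#' @param x,object a \code{DomainSelection}
#' @export
setGeneric("domainSize", function(x) standardGeneric("domainSize"))
#' @rdname DomainSelection-class
#' @export
setMethod("domainSize", "DomainSelection", function(x) length(x@indices))

#' @rdname DomainSelection-class
#' @export
setGeneric("domainIndices", function(x) standardGeneric("domainIndices"))
#' @rdname DomainSelection-class
#' @export
setMethod("domainIndices", "DomainSelection", function(x) x@indices)

#' @rdname CaStructure-class
#' @param x,object a \code{CaStructure}
#' @export
setGeneric("caCount", function(x) standardGeneric("caCount"))
#' @rdname CaStructure-class
#' @export
setMethod("caCount", "CaStructure", function(x) length(x@caIdx))
#' @rdname CaTrajectory-class
#' @export
setMethod("caCount", "CaTrajectory", function(x) dim(x@coords)[1])

#' C-alpha coordinates of a structure (nm), in renumbered order
#' @param x a \code{CaStructure}
#' @param selection optional \code{DomainSelection} restricting the rows
#' @return numeric matrix (N x 3)
#' @export
caCoords <- function(x, selection = NULL) {
    stopifnot(is(x, "CaStructure"))
    m <- x@xyz[x@caIdx, , drop = FALSE]
    if (!is.null(selection)) {
        idx <- domainIndices(selection)
        if (max(idx) > nrow(m))
            stop("selection index ", max(idx), " exceeds C-alpha count ",
                 nrow(m))
        m <- m[idx, , drop = FALSE]
    }
    dimnames(m) <- NULL
    m
}

#' @rdname CaTrajectory-class
#' @param x,object a \code{CaTrajectory}
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname CaTrajectory-class
#' @export
setMethod("nFrames", "CaTrajectory", function(x) dim(x@coords)[3])

#' Coordinates of one trajectory frame (nm)
#' @param x a \code{CaTrajectory}
#' @param frame 1-based frame index
#' @param selection optional \code{DomainSelection}
#' @return numeric matrix (N x 3)
#' @export
frameCoords <- function(x, frame, selection = NULL) {
    stopifnot(is(x, "CaTrajectory"), frame >= 1, frame <= nFrames(x))
    m <- x@coords[, , frame]
    if (!is.null(selection))
        m <- m[domainIndices(selection), , drop = FALSE]
    m
}

#' Time step of a trajectory in ps
#' @param x a \code{CaTrajectory}
#' @export
timeStepPs <- function(x) x@timeStepPs

#' @rdname ReferenceAxes-class
#' @param x,object a \code{ReferenceAxes}
#' @export
setGeneric("centralFrame", function(x) standardGeneric("centralFrame"))
#' @rdname ReferenceAxes-class
#' @export
setMethod("centralFrame", "ReferenceAxes", function(x) x@centralFrame)

#' Axis matrix of a triad (columns v1, v2, v3)
#' @param x an \code{AxesTriad} or \code{ReferenceAxes}
#' @export
axesMatrix <- function(x) {
    if (is(x, "ReferenceAxes")) x@triad@axes else x@axes
}

#' Eigenvalues (nm^2) of a PCA-derived triad
#' @param x an \code{AxesTriad} or \code{ReferenceAxes}
#' @export
axesEigenvalues <- function(x) {
    if (is(x, "ReferenceAxes")) x@triad@eigenvalues else x@eigenvalues
}

setMethod("show", "DomainSelection", function(object) {
    cat("DomainSelection \"", object@name, "\": ", length(object@indices),
        " C-alpha atoms, range ", min(object@indices), "-",
        max(object@indices), "\n", sep = "")
})

setMethod("show", "CaStructure", function(object) {
    cat("CaStructure: ", nrow(object@atoms), " atoms, ",
        length(object@caIdx), " C-alpha (renumbered 1-",
        length(object@caIdx), "), coordinates in nm\n", sep = "")
})

setMethod("show", "CaTrajectory", function(object) {
    d <- dim(object@coords)
    cat("CaTrajectory: ", d[3], " frames x ", d[1], " C-alpha atoms, ",
        object@timeStepPs, " ps/frame (total ",
        format(d[3] * object@timeStepPs / 1000, digits = 4), " ns)\n",
        sep = "")
})

setMethod("show", "AxesTriad", function(object) {
    cat("AxesTriad (columns v1 v2 v3), det =",
        format(det(object@axes), digits = 4), "\n")
    print(round(object@axes, 4))
    if (!anyNA(object@eigenvalues))
        cat("eigenvalues (nm^2):",
            paste(format(object@eigenvalues, digits = 4), collapse = ", "),
            "\n")
})

setMethod("show", "ReferenceAxes", function(object) {
    cat("ReferenceAxes for domain \"", object@domain@name,
        "\": central frame k = ", object@centralFrame, "\n", sep = "")
    show(object@triad)
})

setMethod("show", "OrientationSeries", function(object) {
    cat("OrientationSeries ", object@domainV, " vs ", object@domainW, ": ",
        length(object@frames), " frames\n", sep = "")
    if (length(object@frames)) {
        cat("  d(f) [nm]: ", format(mean(object@distance), digits = 4),
            " (mean), range ",
            paste(format(range(object@distance), digits = 4),
                  collapse = " - "), "\n", sep = "")
        cat("  mean cosines:",
            paste(format(colMeans(object@cosines), digits = 3),
                  collapse = ", "), "\n")
    }
})

setMethod("show", "MotionSpec", function(object) {
    cat("MotionSpec: ", object@angleType, " rotation about (",
        paste(format(object@axis, digits = 3), collapse = ", "),
        "), noise sigma = ", object@sigmaNm, " nm\n", sep = "")
})
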