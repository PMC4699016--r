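## Pure rigid-body mathematics: centres, Kabsch superposition, PCA-derived
## local axes, orientation disambiguation, relative rotations, directional
## cosines and x-convention Euler angles. All coordinates in nm, all
## user-facing angles in degrees.

.RAD2DEG <- 180 / pi
.DEG2RAD <- pi / 180

.clamp1 <- function(x) pmin(1, pmax(-1, x))

.checkRotation <- function(R, tol = 1e-9, what = "rotation matrix") {
    if (!is.matrix(R) || any(dim(R) != c(3L, 3L)))
        stop(what, " must be 3 x 3")
    if (max(abs(R %*% t(R) - diag(3))) >= tol)
        stop(what, " is not orthonormal within ", tol)
    if (abs(det(R) - 1) >= max(tol, 1e-9))
        stop(what, " has det != +1 (improper rotation)")
    invisible(R)
}

#' Geometric centre of a point set
#'
#' Arithmetic mean of the C-alpha coordinates of a domain (nm), the
#' domain's centre used for inter-domain distances.
#'
#' @param coords numeric matrix (N x 3), N >= 1.
#' @return numeric 3-vector.
#' @export
geometricCenter <- function(coords) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 1L || ncol(coords) != 3L)
        stop("coords must be a non-empty N x 3 matrix")
    colMeans(coords)
}

#' Distance between the centres of two domains
#'
#' Euclidean norm of the difference of the two geometric centres;
#' symmetric in its arguments and invariant under any common rigid motion.
#'
#' @param coordsV,coordsW numeric matrices (N x 3), nm.
#' @return distance in nm.
#' @export
centerDistance <- function(coordsV, coordsW) {
    sqrt(sum((geometricCenter(coordsW) - geometricCenter(coordsV))^2))
}

#' Kabsch least-squares superposition
#'
#' Closed-form rigid fit of point set P onto Q (matched row order):
#' the proper rotation R (det = +1, reflections excluded via the
#' singular-value sign correction) and translation t minimising the RMSD
#' of R p_i + t against q_i.
#'
#' @param P,Q numeric matrices (N x 3), N >= 3, matched ordering.
#' @return list with elements `R` (3 x 3 rotation mapping centred P onto
#'   centred Q), `t` (3-vector, so that `Q ~ P %*% t(R) + t`), and `rmsd`
#'   (nm) actually achieved.
#' @export
kabsch <- function(P, Q) {
    P <- as.matrix(P); Q <- as.matrix(Q)
    if (!all(dim(P) == dim(Q))) stop("P and Q must have equal dimensions")
    if (nrow(P) < 3L) stop("need at least 3 points for a unique rotation")
    pc <- colMeans(P); qc <- colMeans(Q)
    Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
    H <- crossprod(Pc, Qc)
    sv <- svd(H)
    if (sv$d[3] < 1e-12)
        warning("near-degenerate (collinear or coincident) point set: ",
                "rotation may be non-unique")
    d <- sign(det(tcrossprod(sv$v, sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    e <- sum(Pc^2) + sum(Qc^2) - 2 * (sv$d[1] + sv$d[2] + d * sv$d[3])
    list(R = R, t = as.numeric(qc - R %*% pc),
         rmsd = sqrt(max(e, 0) / nrow(P)))
}

#' Principal-axis triad of a domain
#'
#' Orthonormal eigenvectors of the covariance matrix of the (internally
#' centred) coordinates, columns sorted by descending eigenvalue. Column
#' signs are arbitrary at this stage: eigenvector orientation is not well
#' defined and must be fixed by [disambiguateAxes()] (never by per-frame
#' heuristics, which is precisely the artifact this package avoids).
#'
#' Near-equal consecutive eigenvalues are reported with a warning: for an
#' almost cylindrical domain the second and third axes may interchange
#' roles between decompositions.
#'
#' @param coords numeric matrix (N x 3), N >= 3, nm.
#' @return an [AxesTriad-class] (sign-ambiguous).
#' @export
pcaAxes <- function(coords) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 3L) stop("need at least 3 atoms for PCA axes")
    cc <- sweep(coords, 2, colMeans(coords))
    covm <- crossprod(cc) / (nrow(cc) - 1L)
    e <- eigen(covm, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    if (any(diff(ev) > -1e-12 & abs(diff(ev)) < 1e-12))
        warning("near-degenerate eigenvalues: axis identity is unstable")
    V <- e$vectors
    V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    new("AxesTriad", axes = V, eigenvalues = ev)
}

.orientSign <- function(v, coords, pair, axisName) {
    refvec <- coords[pair[2], ] - coords[pair[1], ]
    nrm <- sqrt(sum(refvec^2))
    if (nrm < 1e-12)
        stop("disambiguation pair for ", axisName, " is coincident")
    d <- sum(v * refvec) / nrm
    if (abs(d) < 1e-8)
        stop("reference vector for ", axisName, " is orthogonal to the ",
             "axis; choose a different atom pair")
    if (d < 0) -v else v
}

#' Default atom pairs for axis-orientation disambiguation
#'
#' Deterministic defaults when the user names none: for v1 the (first,
#' last) atom of the domain, orienting v1 along the chain direction; for
#' v2 the atom nearest the domain centre paired with the atom at the
#' largest perpendicular distance from the v1 axis.
#'
#' @param coords domain coordinates (N x 3, nm).
#' @param v1 current first axis (unit 3-vector).
#' @return list with integer pairs `pair1`, `pair2` (in-domain indices).
#' @export
defaultOrientationPairs <- function(coords, v1) {
    coords <- as.matrix(coords)
    n <- nrow(coords)
    ctr <- colMeans(coords)
    cc <- sweep(coords, 2, ctr)
    along <- as.numeric(cc %*% v1)
    perp2 <- rowSums(cc^2) - along^2
    near <- which.min(rowSums(cc^2))
    far <- which.max(perp2)
    if (near == far) near <- setdiff(order(rowSums(cc^2)), far)[1]
    list(pair1 = c(1L, n), pair2 = c(near, far))
}

#' Fix eigenvector orientations against in-domain atom pairs
#'
#' PCA yields axes unique in direction but ambiguous in orientation. The
#' orientation of v1 is set so that its cosine with the vector joining a
#' chosen pair of C-alpha atoms is positive; likewise v2 with a second
#' pair; v3 is then recomputed as v1 x v2, making the triad exactly
#' right-handed (det = +1).
#'
#' @param triad an [AxesTriad-class] (e.g. from [pcaAxes()]).
#' @param coords the domain coordinates the triad was derived from.
#' @param pair1,pair2 integer pairs of in-domain atom indices; defaults
#'   from [defaultOrientationPairs()].
#' @return an [AxesTriad-class] with det = +1.
#' @export
disambiguateAxes <- function(triad, coords, pair1 = NULL, pair2 = NULL) {
    stopifnot(is(triad, "AxesTriad"))
    coords <- as.matrix(coords)
    T <- triad@axes
    if (is.null(pair1) || is.null(pair2)) {
        dp <- defaultOrientationPairs(coords, T[, 1])
        if (is.null(pair1)) pair1 <- dp$pair1
        if (is.null(pair2)) pair2 <- dp$pair2
    }
    if (pair1[1] == pair1[2] || pair2[1] == pair2[2])
        stop("disambiguation pairs must be distinct atom indices")
    v1 <- .orientSign(T[, 1], coords, pair1, "v1")
    v2 <- .orientSign(T[, 2], coords, pair2, "v2")
    v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    new("AxesTriad", axes = cbind(v1, v2, v3, deparse.level = 0),
        eigenvalues = triad@eigenvalues)
}

#' Align a triad's orientation to a reference triad
#'
#' Standardises the second domain's reference axes against the first's:
#' w1 and w2 are flipped, if necessary, so that v1.w1 >= 0 and
#' v2.w2 >= 0, and w3 is recomputed as w1 x w2. Applied once, to the
#' reference axes only -- per-frame re-flipping would reintroduce the
#' orientation-switching artifact the axis-transport construction avoids.
#'
#' @param triadW triad to align ([AxesTriad-class]).
#' @param triadV reference triad.
#' @return aligned [AxesTriad-class].
#' @export
alignAxesToReference <- function(triadW, triadV) {
    stopifnot(is(triadW, "AxesTriad"), is(triadV, "AxesTriad"))
    W <- triadW@axes; V <- triadV@axes
    for (i in 1:2) {
        d <- sum(V[, i] * W[, i])
        if (d == 0)
            warning("exact zero cosine for axis ", i,
                    ": keeping current sign")
        else if (d < 0) W[, i] <- -W[, i]
    }
    w3 <- c(W[2, 1] * W[3, 2] - W[3, 1] * W[2, 2],
            W[3, 1] * W[1, 2] - W[1, 1] * W[3, 2],
            W[1, 1] * W[2, 2] - W[2, 1] * W[1, 2])
    W[, 3] <- w3
    new("AxesTriad", axes = W, eigenvalues = triadW@eigenvalues)
}

#' Relative rotation between two triads
#'
#' R_VW = T_W T_V^T, the rotation carrying the axes of domain V onto
#' those of domain W (the inverse of an orthogonal matrix being its
#' transpose). Satisfies T_W = R_VW T_V to machine precision.
#'
#' @param triadV,triadW [AxesTriad-class] objects or 3 x 3 matrices with
#'   orthonormal columns and det = +1.
#' @return 3 x 3 rotation matrix.
#' @export
relativeRotation <- function(triadV, triadW) {
    V <- if (is(triadV, "AxesTriad")) triadV@axes else triadV
    W <- if (is(triadW, "AxesTriad")) triadW@axes else triadW
    .checkRotation(V, 1e-8, "T_V")
    .checkRotation(W, 1e-8, "T_W")
    W %*% t(V)
}

#' Directional cosines between corresponding axes
#'
#' c_i = v_i . w_i for i = 1, 2, 3; +1 means parallel, -1 antiparallel.
#'
#' @param triadV,triadW [AxesTriad-class] objects or 3 x 3 matrices.
#' @return numeric 3-vector in [-1, 1].
#' @export
directionCosines <- function(triadV, triadW) {
    V <- if (is(triadV, "AxesTriad")) triadV@axes else triadV
    W <- if (is(triadW, "AxesTriad")) triadW@axes else triadW
    .clamp1(colSums(V * W))
}

#' Euler angles (x-convention) from a rotation matrix
#'
#' With the rotation written row-wise as r1 = (r1x, r1y, r1z), etc., the
#' angles are alpha = arccos(r3y / sqrt(1 - r3z^2)), beta = arccos(r3z),
#' gamma = arccos(r2y / sqrt(1 - r3z^2)), reported in degrees, each in
#' [0, 180] by the arccos range. Arguments are clamped to [-1, 1] to
#' absorb round-off.
#'
#' At gimbal lock (beta = 0 or 180 degrees within 1e-12 of 1 - r3z^2 = 0)
#' alpha and gamma are not separately identifiable; the convention here
#' folds the whole in-plane rotation into alpha = arccos(r1x) and sets
#' gamma = 0, making the extraction total. The identity then maps to
#' (0, 0, 0).
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return named numeric vector c(alpha, beta, gamma) in degrees.
#' @export
eulerXConvention <- function(R) {
    .checkRotation(R, 1e-8)
    r3z <- .clamp1(R[3, 3])
    s2 <- 1 - r3z^2
    beta <- acos(r3z)
    if (s2 < 1e-12) {
        alpha <- acos(.clamp1(R[1, 1]))
        gamma <- 0
    } else {
        s <- sqrt(s2)
        alpha <- acos(.clamp1(R[3, 2] / s))
        gamma <- acos(.clamp1(R[2, 2] / s))
    }
    c(alpha = alpha, beta = beta, gamma = gamma) * .RAD2DEG
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation by `angleDeg`
#' degrees about the unit vector `axis`.
#'
#' @param axis 3-vector (normalised internally).
#' @param angleDeg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angleDeg) {
    u <- axis / sqrt(sum(axis^2))
    th <- angleDeg * .DEG2RAD
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Compose a rotation with prescribed x-convention Euler angles
#'
#' Constructs the canonical rotation whose [eulerXConvention()] extraction
#' returns exactly (alpha, beta, gamma): R = Rz(psi) Rx(beta) Rz(alpha),
#' where the auxiliary angle psi is solved (principal branch) from
#' sin(beta) cos(gamma) = cos(psi) cos(beta) cos(alpha) -
#' sin(psi) sin(alpha). The three arccos-extracted angles determine a
#' rotation only up to discrete branch choices, so this composition fixes
#' the canonical representative; it exists iff
#' sin(beta)^2 cos(gamma)^2 <= cos(beta)^2 cos(alpha)^2 + sin(alpha)^2
#' (returns NA-filled matrix otherwise, with a warning).
#'
#' @param alphaDeg,betaDeg,gammaDeg angles in degrees, each in [0, 180];
#'   betaDeg must be off gimbal lock (strictly inside (0, 180)).
#' @return 3 x 3 rotation matrix, or NA matrix if the triple is not
#'   realisable.
#' @export
eulerToRotation <- function(alphaDeg, betaDeg, gammaDeg) {
    a <- alphaDeg * .DEG2RAD; b <- betaDeg * .DEG2RAD
    g <- gammaDeg * .DEG2RAD
    if (sin(b)^2 < 1e-12)
        stop("betaDeg is at gimbal lock; the triple does not determine ",
             "a unique rotation")
    A <- cos(b) * cos(a); B <- -sin(a); C <- sin(b) * cos(g)
    h <- sqrt(A^2 + B^2)
    if (h < abs(C)) {
        warning("Euler triple is not realisable as a rotation")
        return(matrix(NA_real_, 3, 3))
    }
    psi <- atan2(B, A) + acos(.clamp1(C / h))
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t),
                               0, -sin(t), cos(t)), 3, 3)
    Rz(psi) %*% Rx(b) %*% Rz(a)
}

#' Draw a uniformly random proper rotation
#'
#' QR-based Haar sampling with the sign correction giving det = +1.
#' Uses the current RNG state.
#'
#' @return 3 x 3 rotation matrix.
#' @export
randomRotation <- function() {
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    Q
}
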