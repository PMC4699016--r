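test_that("geometric centre and centre distance behave as means/norms", {
    expect_equal(geometricCenter(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
    p <- c(0.3, -1.2, 5)
    expect_equal(geometricCenter(rbind(p)), p)
    expect_equal(geometricCenter(rbind(c(1, 1, 1), c(-1, -1, -1),
                                       c(0, 0, 0))), c(0, 0, 0))
    expect_error(geometricCenter(matrix(numeric(0), 0, 3)), "non-empty")

    A <- rbind(c(0, 0, 0), c(0, 0, 0))
    B <- rbind(c(0, 0, 1), c(0, 0, 1))
    expect_equal(centerDistance(A, B), 1)
    expect_equal(centerDistance(A, B), centerDistance(B, A))
    expect_equal(centerDistance(A, A), 0)
    expect_equal(centerDistance(rbind(c(1, 2, 2)), rbind(c(0, 0, 0))), 3)
})

test_that("kabsch recovers constructed rigid transforms and matches oracles", {
    set.seed(42)
    for (i in 1:25) {
        P <- matrix(rnorm(3 * 8), 8, 3)
        R0 <- randomRotation()
        t0 <- rnorm(3)
        Q <- sweep(P %*% t(R0), 2, t0, "+")
        fit <- kabsch(P, Q)
        expect_lt(max(abs(fit$R - R0)), 1e-9)
        expect_lt(max(abs(fit$t - t0)), 1e-9)
        expect_lt(fit$rmsd, 1e-7)
        expect_lt(max(abs(crossprod(fit$R) - diag(3))), 1e-9)
        expect_equal(det(fit$R), 1, tolerance = 1e-9)
    }
    # identity case
    P <- matrix(rnorm(12), 4, 3)
    fit <- kabsch(P, P)
    expect_equal(fit$R, diag(3), tolerance = 1e-12)
    expect_equal(fit$t, c(0, 0, 0), tolerance = 1e-12)
    expect_equal(fit$rmsd, 0, tolerance = 1e-12)
})

test_that("kabsch on noisy pairs matches an independent numerical minimiser", {
    set.seed(7)
    P <- matrix(rnorm(12), 4, 3)
    Q <- P %*% t(rotationAboutAxis(c(1, 2, 3), 25)) +
        matrix(rnorm(12, sd = 0.1), 4, 3)
    fit <- kabsch(P, Q)
    # oracle: direct minimisation of RMSD over z-x-z angles + translation,
    # refined from a coarse angle grid
    obj <- function(par) {
        Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                                   0, 0, 1), 3, 3)
        Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t),
                                   0, -sin(t), cos(t)), 3, 3)
        R <- Rz(par[1]) %*% Rx(par[2]) %*% Rz(par[3])
        M <- sweep(P %*% t(R), 2, par[4:6], "+")
        sqrt(mean(rowSums((M - Q)^2)))
    }
    grid <- expand.grid(a = seq(0, 2 * pi, length.out = 9),
                        b = seq(0, pi, length.out = 5),
                        g = seq(0, 2 * pi, length.out = 9))
    vals <- apply(grid, 1, function(g0) obj(c(g0, 0, 0, 0)))
    best <- as.numeric(grid[which.min(vals), ])
    opt <- optim(c(best, 0, 0, 0), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 2000))
    expect_equal(fit$rmsd, opt$value, tolerance = 1e-3)
    # cross-check against bio3d's superposition
    fitted <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(Q)), as.numeric(t(P))))
    rmsdB <- sqrt(mean(rowSums(
        (matrix(fitted, ncol = 3, byrow = TRUE) - Q)^2)))
    expect_equal(fit$rmsd, rmsdB, tolerance = 1e-6)
})

test_that("kabsch is invariant under a common rigid transform", {
    set.seed(11)
    P <- matrix(rnorm(18), 6, 3)
    Q <- P %*% t(rotationAboutAxis(c(0, 1, 0), 40)) +
        matrix(rnorm(18, sd = 0.05), 6, 3)
    base <- kabsch(P, Q)$rmsd
    R0 <- randomRotation(); t0 <- rnorm(3)
    moved <- kabsch(sweep(P %*% t(R0), 2, t0, "+"),
                    sweep(Q %*% t(R0), 2, t0, "+"))$rmsd
    expect_equal(base, moved, tolerance = 1e-9)
    expect_warning(kabsch(cbind(1:5, 0, 0), cbind(1:5, 0, 0)),
                   "degenerate")
})

test_that("pcaAxes sorts descending, handles rank deficiency, finds helix axis", {
    z <- cbind(0, 0, seq(0, 3, length.out = 10))
    tz <- suppressWarnings(pcaAxes(z))
    expect_equal(abs(axesMatrix(tz)[, 1]), c(0, 0, 1), tolerance = 1e-12)
    expect_equal(axesEigenvalues(tz)[2:3], c(0, 0), tolerance = 1e-12)

    set.seed(3)
    xy <- cbind(rnorm(20), rnorm(20), 0)
    expect_equal(abs(axesMatrix(pcaAxes(xy))[, 3]), c(0, 0, 1),
                 tolerance = 1e-12)

    hel <- makeIdealHelix(25)
    v1 <- axesMatrix(pcaAxes(hel))[, 1]
    # oracle: the helical axis by linear regression of x,y on z
    fitx <- lm(hel[, 1] ~ hel[, 3]); fity <- lm(hel[, 2] ~ hel[, 3])
    axis <- c(coef(fitx)[2], coef(fity)[2], 1)
    axis <- axis / sqrt(sum(axis^2))
    ang <- acos(abs(sum(v1 * axis))) * 180 / pi
    expect_lt(ang, 5)
    ev <- axesEigenvalues(pcaAxes(hel))
    expect_true(all(diff(ev) <= 1e-12) && all(ev >= 0))
})

test_that("disambiguation fixes signs against atom pairs and right-handedness", {
    hel <- makeIdealHelix(20)
    tri <- pcaAxes(hel)
    # force v1 against the chain direction, then disambiguate
    T <- axesMatrix(tri)
    if (sum(T[, 1] * (hel[20, ] - hel[1, ])) > 0) T[, 1] <- -T[, 1]
    flipped <- new("AxesTriad", axes = T, eigenvalues = axesEigenvalues(tri))
    fixed <- disambiguateAxes(flipped, hel, pair1 = c(1L, 20L))
    expect_gt(sum(axesMatrix(fixed)[, 1] * (hel[20, ] - hel[1, ])), 0)
    expect_equal(det(axesMatrix(fixed)), 1, tolerance = 1e-12)
    # already-positive axis is unchanged
    again <- disambiguateAxes(fixed, hel, pair1 = c(1L, 20L))
    expect_equal(axesMatrix(again)[, 1], axesMatrix(fixed)[, 1])
    # orthogonal reference pair errors
    expect_error(
        suppressWarnings(disambiguateAxes(pcaAxes(cbind(0, 0, 1:10)),
                         cbind(0, 0, 1:10),
                         pair1 = c(1L, 2L), pair2 = c(1L, 2L))),
        "orthogonal")

    set.seed(5)
    for (i in 1:200) {
        pts <- matrix(rnorm(30), 10, 3)
        out <- disambiguateAxes(pcaAxes(pts), pts)
        expect_equal(det(axesMatrix(out)), 1, tolerance = 1e-9)
        M <- axesMatrix(out)
        expect_equal(M[, 3], c(M[2, 1] * M[3, 2] - M[3, 1] * M[2, 2],
                               M[3, 1] * M[1, 2] - M[1, 1] * M[3, 2],
                               M[1, 1] * M[2, 2] - M[2, 1] * M[1, 2]),
                     tolerance = 1e-12)
    }
})

test_that("reference alignment enforces positive leading cosines", {
    set.seed(8)
    for (i in 1:100) {
        pts <- matrix(rnorm(30), 10, 3)
        V <- disambiguateAxes(pcaAxes(pts), pts)
        W0 <- axesMatrix(V)
        flip <- sample(c(1, -1), 2, replace = TRUE)
        W0[, 1] <- flip[1] * W0[, 1]; W0[, 2] <- flip[2] * W0[, 2]
        W0[, 3] <- flip[1] * flip[2] * W0[, 3]
        W <- new("AxesTriad", axes = W0, eigenvalues = rep(NA_real_, 3))
        A <- alignAxesToReference(W, V)
        cc <- directionCosines(V, A)
        expect_true(cc[1] >= 0 && cc[2] >= 0)
        expect_equal(det(axesMatrix(A)), 1, tolerance = 1e-9)
    }
    # identical triads unchanged with cosines (1,1,1)
    pts <- matrix(rnorm(30), 10, 3)
    V <- disambiguateAxes(pcaAxes(pts), pts)
    expect_equal(directionCosines(V, alignAxesToReference(V, V)),
                 c(1, 1, 1), tolerance = 1e-12)
})

test_that("relative rotation satisfies the transport identity", {
    set.seed(13)
    pts <- matrix(rnorm(30), 10, 3)
    TV <- axesMatrix(disambiguateAxes(pcaAxes(pts), pts))
    expect_equal(relativeRotation(TV, TV), diag(3), tolerance = 1e-12)
    R0 <- randomRotation()
    TW <- R0 %*% TV
    expect_lt(max(abs(relativeRotation(TV, TW) - R0)), 1e-9)
    expect_lt(max(abs(relativeRotation(TW, TV) -
                      t(relativeRotation(TV, TW)))), 1e-12)
    R <- relativeRotation(TV, TW)
    expect_lt(max(abs(TW - R %*% TV)), 1e-9)
    expect_error(relativeRotation(TV * 2, TW), "orthonormal")
})

test_that("direction cosines: identity, flips and closed-form rotation", {
    pts <- makeIdealHelix(15)
    V <- axesMatrix(disambiguateAxes(pcaAxes(pts), pts))
    expect_equal(directionCosines(V, V), c(1, 1, 1), tolerance = 1e-12)
    W <- V; W[, 1] <- -W[, 1]
    expect_equal(directionCosines(V, W), c(-1, 1, 1), tolerance = 1e-12)
    for (th in c(10, 45, 120)) {
        W <- rotationAboutAxis(V[, 1], th) %*% V
        expect_equal(directionCosines(V, W),
                     c(1, cos(th * pi / 180), cos(th * pi / 180)),
                     tolerance = 1e-12)
    }
})

test_that("Euler extraction: identity, 90-deg-about-x, range property", {
    expect_equal(eulerXConvention(diag(3)),
                 c(alpha = 0, beta = 0, gamma = 0))
    R <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
    expect_equal(unname(eulerXConvention(R)), c(0, 90, 90),
                 tolerance = 1e-12)
    set.seed(17)
    for (i in 1:500) {
        ang <- eulerXConvention(randomRotation())
        expect_true(all(ang >= 0 & ang <= 180))
    }
})

test_that("Euler composition inverts extraction on the representable family", {
    set.seed(19)
    n <- 0
    while (n < 300) {
        a <- runif(1, 1, 179); b <- runif(1, 1, 179); g <- runif(1, 1, 179)
        R <- suppressWarnings(eulerToRotation(a, b, g))
        if (anyNA(R)) next
        n <- n + 1
        expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
        ang <- eulerXConvention(R)
        expect_equal(unname(ang), c(a, b, g), tolerance = 1e-6)
        expect_lt(max(abs(eulerToRotation(ang[1], ang[2], ang[3]) - R)),
                  1e-6)
    }
    expect_error(eulerToRotation(10, 0, 10), "gimbal")
})
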