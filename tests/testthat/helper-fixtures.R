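# Shared fixtures: tiny PDB writers, independent oracles and synthetic
# complex builders. Everything is generated in code at test time.

# Write a minimal C-alpha-only PDB; coords in Angstrom, one model per
# element of `models` (a list of N x 3 matrices).
writeCaPdb <- function(path, models, chain = "A",
                       resno = seq_len(nrow(models[[1]]))) {
    if (is.matrix(models)) models <- list(models)
    chain <- rep_len(chain, nrow(models[[1]]))
    con <- file(path, "w")
    on.exit(close(con))
    multi <- length(models) > 1L
    for (m in seq_along(models)) {
        if (multi) writeLines(sprintf("MODEL     %4d", m), con)
        x <- models[[m]]
        for (i in seq_len(nrow(x)))
            writeLines(sprintf(
                "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                i, chain[i], resno[i], x[i, 1], x[i, 2], x[i, 3]), con)
        if (multi) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

# Independent brute-force central-frame oracle: double loop of R-level
# Kabsch fits over the analysed frame subset.
bruteCentralFrame <- function(traj, sel, stride = 1L) {
    frames <- seq(1L, nFrames(traj), by = stride)
    m <- length(frames)
    prof <- numeric(m)
    for (a in seq_len(m)) {
        for (b in seq_len(m)) {
            if (a == b) next
            prof[a] <- prof[a] +
                kabsch(frameCoords(traj, frames[a], sel),
                       frameCoords(traj, frames[b], sel))$rmsd
        }
    }
    list(k = frames[which.min(prof)], profile = prof, frames = frames)
}

# Synthetic stand-in complex with the packaged chain layout: host carries
# chains A-E (TCR/pMHC part), the donor carries its own MHC copy (chain
# A, rigidly displaced) plus the two CD8 chains F and G.
makeSyntheticComplex <- function(seed = 1) {
    set.seed(seed)
    tab <- tcrPmhcCd8Domains("chains")
    sizes <- tab$computedLength
    names(sizes) <- tab$chain
    mkChain <- function(n, centre) {
        sweep(matrix(rnorm(3 * n, sd = 1), n, 3), 2, centre, "+")
    }
    hostXyz <- do.call(rbind, lapply(seq_len(5), function(i)
        mkChain(sizes[i], c(3 * i, 0, 0))))
    host <- caStructure(hostXyz, chain = rep(tab$chain[1:5], sizes[1:5]))
    # donor: same MHC coordinates plus CD8 chains, all under one random
    # rigid displacement (the true pose the graft must undo)
    mhc <- hostXyz[seq_len(sizes["A"]), , drop = FALSE]
    cd8 <- rbind(mkChain(sizes["F"], c(2, 4, 0)),
                 mkChain(sizes["G"], c(4, 4, 0)))
    R0 <- randomRotation()
    t0 <- c(5, -3, 2)
    donorXyz <- sweep(rbind(mhc, cd8) %*% t(R0), 2, t0, "+")
    donor <- caStructure(donorXyz,
                         chain = rep(c("A", "F", "G"),
                                     sizes[c("A", "F", "G")]))
    list(host = host, donor = donor, cd8True = cd8,
         nMhc = unname(sizes["A"]))
}
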