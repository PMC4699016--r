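## Assembly of a composite complex by superposition on a shared domain:
## locate a binding interface by a distance cutoff, then graft a donor
## structure onto a host by a Kabsch fit of the shared selection and drop
## the donor's redundant copy.

#' C-alpha atoms of one structure within a cutoff of another
#'
#' Returns the C-alpha atoms of `selA` in `structA` whose minimum
#' distance to `structB`'s atoms (C-alpha of `selB` by default, or all
#' atoms of the selected residues) is at most `cutoffNm`. Used to
#' localise a binding interface, e.g. the coreceptor footprint on an MHC
#' at 0.8 nm.
#'
#' @param structA,structB [CaStructure-class] objects.
#' @param selA,selB [DomainSelection-class] objects (C-alpha indices;
#'   default: all C-alpha atoms of the structure).
#' @param cutoffNm distance cutoff in nm (> 0), default 0.8.
#' @param bAtoms `"ca"` (default) measures to C-alpha atoms of selB;
#'   `"all"` measures to every atom of selB's residues.
#' @return a [DomainSelection-class] of the interface C-alpha indices of
#'   `structA`, or NULL (with a warning) when no atom is within reach.
#' @export
findInterface <- function(structA, selA = NULL, structB, selB = NULL,
                          cutoffNm = 0.8, bAtoms = c("ca", "all")) {
    bAtoms <- match.arg(bAtoms)
    stopifnot(is(structA, "CaStructure"), is(structB, "CaStructure"),
              cutoffNm > 0)
    idxA <- if (is.null(selA)) seq_len(caCount(structA))
            else domainIndices(selA)
    A <- caCoords(structA)[idxA, , drop = FALSE]
    if (bAtoms == "ca") {
        idxB <- if (is.null(selB)) seq_len(caCount(structB))
                else domainIndices(selB)
        B <- caCoords(structB)[idxB, , drop = FALSE]
    } else {
        caRows <- if (is.null(selB)) structB@caIdx
                  else structB@caIdx[domainIndices(selB)]
        resKey <- paste(structB@atoms$chain, structB@atoms$resno)
        keep <- resKey %in% resKey[caRows]
        B <- structB@xyz[keep, , drop = FALSE]
    }
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    hit <- sqrt(pmax(apply(d2, 1, min), 0)) <= cutoffNm
    if (!any(hit)) {
        warning("no interface found within ", cutoffNm, " nm")
        return(NULL)
    }
    new("DomainSelection", name = "interface",
        indices = sort(as.integer(idxA[hit])))
}

#' Graft a donor structure onto a host via a shared domain
#'
#' Rigid-transforms the donor by the Kabsch superposition of its shared
#' selection onto the host's (positional i-th-to-i-th correspondence;
#' residue-name mismatches only warn), removes the residues in `drop`
#' (the donor's redundant copy of the shared molecule) from the
#' transformed donor, and merges host and remaining donor into one
#' structure with the C-alpha renumbering re-run over the concatenation.
#' Idempotent when the donor is already superposed.
#'
#' @param host,donor [CaStructure-class] objects.
#' @param sharedHost,sharedDonor equal-size [DomainSelection-class]
#'   objects naming the shared C-alpha atoms in each structure.
#' @param drop optional [DomainSelection-class] of donor C-alpha indices
#'   whose residues are removed after superposition.
#' @param rmsdWarnNm warn when the superposition RMSD exceeds this (nm).
#' @return list with `structure` (the merged [CaStructure-class]) and
#'   `rmsd` (superposition RMSD, nm).
#' @export
graftBySharedDomain <- function(host, donor, sharedHost, sharedDonor,
                                drop = NULL, rmsdWarnNm = 0.2) {
    stopifnot(is(host, "CaStructure"), is(donor, "CaStructure"))
    if (domainSize(sharedHost) != domainSize(sharedDonor))
        stop("shared selections differ in size (",
             domainSize(sharedHost), " vs ", domainSize(sharedDonor), ")")
    hIdx <- domainIndices(sharedHost); dIdx <- domainIndices(sharedDonor)
    hRes <- host@atoms$resid[host@caIdx[hIdx]]
    dRes <- donor@atoms$resid[donor@caIdx[dIdx]]
    if (any(hRes != dRes))
        warning(sum(hRes != dRes), " residue-name mismatch(es) in the ",
                "shared selection; correspondence is positional")
    fit <- kabsch(caCoords(donor)[dIdx, , drop = FALSE],
                  caCoords(host)[hIdx, , drop = FALSE])
    if (fit$rmsd > rmsdWarnNm)
        warning("shared-domain superposition RMSD ",
                format(fit$rmsd, digits = 3), " nm exceeds ", rmsdWarnNm,
                " nm")
    newXyz <- sweep(donor@xyz %*% t(fit$R), 2, fit$t, "+")
    keep <- rep(TRUE, nrow(donor@atoms))
    if (!is.null(drop)) {
        caRows <- donor@caIdx[domainIndices(drop)]
        resKey <- paste(donor@atoms$chain, donor@atoms$resno)
        keep <- !(resKey %in% resKey[caRows])
    }
    atoms <- rbind(host@atoms, donor@atoms[keep, , drop = FALSE])
    atoms$eleno <- seq_len(nrow(atoms))
    xyz <- rbind(host@xyz, newXyz[keep, , drop = FALSE])
    caIdx <- which(atoms$elety == "CA")  # renumbering re-run on the merge
    merged <- new("CaStructure", atoms = atoms, xyz = xyz,
                  caIdx = as.integer(caIdx))
    list(structure = merged, rmsd = fit$rmsd)
}
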