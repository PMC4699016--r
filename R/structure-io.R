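## Structure and trajectory I/O. PDB files are read and written through
## bio3d; coordinates are converted to nm at the boundary (PDB stores
## Angstrom) and kept in nm everywhere downstream. C-alpha atoms are
## renumbered consecutively from 1 across all chains in file order,
## independently of the PDB residue numbering; all selections use these
## indices.

.A2NM <- 0.1
.NM2A <- 10

.atomTable <- function(pdb) {
    data.frame(eleno = pdb$atom$eleno,
               elety = pdb$atom$elety,
               resid = pdb$atom$resid,
               chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
               resno = pdb$atom$resno,
               stringsAsFactors = FALSE)
}

.caRows <- function(atoms) {
    resKey <- paste(atoms$chain, atoms$resno, sep = "/")
    caRow <- which(atoms$elety == "CA")
    haveCa <- unique(resKey[caRow])
    missing <- setdiff(unique(resKey), haveCa)
    if (length(missing))
        warning(length(missing), " residue(s) lack a C-alpha atom and are ",
                "skipped in the renumbering: ",
                paste(head(missing, 5), collapse = ", "),
                if (length(missing) > 5) ", ..." else "")
    caRow
}

#' Read a structure from a PDB file
#'
#' Coordinates are converted from Angstrom to nm. C-alpha atoms receive
#' consecutive 1-based indices across all chains in file order; residues
#' without a C-alpha record are skipped with a warning (only C-alpha
#' atoms enter the analysis).
#'
#' @param path path to a PDB file.
#' @param format currently only `"pdb"`.
#' @return a [CaStructure-class].
#' @export
readStructure <- function(path, format = c("pdb")) {
    format <- match.arg(format)
    pdb <- bio3d::read.pdb(path)
    atoms <- .atomTable(pdb)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) * .A2NM
    new("CaStructure", atoms = atoms, xyz = xyz, caIdx = .caRows(atoms))
}

#' Write a structure to a PDB file
#'
#' Inverse of [readStructure()]: nm coordinates are written as Angstrom.
#' Round-tripping reproduces C-alpha coordinates to the PDB precision of
#' 1e-3 Angstrom.
#'
#' @param x a [CaStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(x, path) {
    stopifnot(is(x, "CaStructure"))
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(x@xyz)) * .NM2A,
                     resno = x@atoms$resno, resid = x@atoms$resid,
                     eleno = x@atoms$eleno, elety = x@atoms$elety,
                     chain = x@atoms$chain)
    invisible(path)
}

.modelAtomCounts <- function(lines) {
    starts <- grep("^MODEL", lines)
    if (!length(starts)) return(NULL)
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
        ends <- c(ends, length(lines))
    vapply(seq_along(starts), function(i)
        sum(grepl("^(ATOM|HETATM)", lines[starts[i]:ends[i]])), integer(1))
}

#' Read a trajectory from a multi-model PDB file
#'
#' Each MODEL block is one frame; a single-model file yields a degenerate
#' one-frame trajectory. All models must share atom count and ordering.
#' Only the C-alpha trace is retained (the analysis considers C-alpha
#' atoms exclusively). The time step is user-supplied since trajectories
#' are commonly subsampled before analysis.
#'
#' @param path path to a (multi-model) PDB file.
#' @param timeStepPs effective time per frame, ps (> 0).
#' @param format currently only `"pdb"`.
#' @return a [CaTrajectory-class].
#' @export
readTrajectory <- function(path, timeStepPs, format = c("pdb")) {
    format <- match.arg(format)
    stopifnot(timeStepPs > 0)
    counts <- .modelAtomCounts(readLines(path))
    if (!is.null(counts) && length(unique(counts)) > 1L) {
        bad <- which(counts != counts[1])[1]
        stop("inconsistent atom count across models: frame ", bad,
             " has ", counts[bad], " atoms, frame 1 has ", counts[1])
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    atoms <- .atomTable(pdb)
    ca <- .caRows(atoms)
    xyz <- pdb$xyz                      # F x 3n, Angstrom
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    F <- nrow(xyz)
    n <- length(ca)
    coords <- array(NA_real_, c(n, 3, F))
    for (f in seq_len(F)) {
        m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
        coords[, , f] <- m[ca, , drop = FALSE] * .A2NM
    }
    new("CaTrajectory", coords = coords, timeStepPs = timeStepPs,
        atoms = atoms[ca, , drop = FALSE])
}

#' Write a C-alpha trajectory as a multi-model PDB file
#'
#' @param x a [CaTrajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(x, path) {
    stopifnot(is(x, "CaTrajectory"))
    F <- nFrames(x)
    n <- caCount(x)
    xyz <- matrix(NA_real_, F, 3 * n)
    for (f in seq_len(F))
        xyz[f, ] <- as.numeric(t(x@coords[, , f])) * .NM2A
    at <- x@atoms
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = at$resno, resid = at$resid,
                     eleno = at$eleno, elety = at$elety, chain = at$chain)
    invisible(path)
}

#' Build a trajectory object from a coordinate array
#'
#' Convenience constructor for programmatically generated trajectories.
#'
#' @param coords numeric array (n_ca x 3 x F), nm.
#' @param timeStepPs time per frame, ps.
#' @param atoms optional data.frame of atom records; a synthetic
#'   poly-alanine record is generated when omitted.
#' @return a [CaTrajectory-class].
#' @export
caTrajectory <- function(coords, timeStepPs, atoms = NULL) {
    n <- dim(coords)[1]
    if (is.null(atoms))
        atoms <- data.frame(eleno = seq_len(n), elety = "CA",
                            resid = "ALA", chain = "A", resno = seq_len(n),
                            stringsAsFactors = FALSE)
    new("CaTrajectory", coords = coords, timeStepPs = timeStepPs,
        atoms = atoms)
}

#' Build a structure object from C-alpha coordinates
#'
#' Convenience constructor for programmatically assembled (synthetic)
#' C-alpha-only structures; chains are laid out in the order given, which
#' fixes the consecutive renumbering.
#'
#' @param xyz numeric matrix (N x 3), nm; one C-alpha per row.
#' @param chain chain identifier per atom (recycled).
#' @param resno residue numbers per atom (default: per-chain 1..n).
#' @param resid residue names (recycled, default "ALA").
#' @return a [CaStructure-class].
#' @export
caStructure <- function(xyz, chain = "A", resno = NULL, resid = "ALA") {
    xyz <- as.matrix(xyz)
    n <- nrow(xyz)
    chain <- rep_len(chain, n)
    if (is.null(resno))
        resno <- as.integer(unlist(lapply(rle(chain)$lengths, seq_len)))
    atoms <- data.frame(eleno = seq_len(n), elety = "CA",
                        resid = rep_len(resid, n), chain = chain,
                        resno = resno, stringsAsFactors = FALSE)
    new("CaStructure", atoms = atoms, xyz = xyz, caIdx = seq_len(n))
}

#' Resolve a range-list selection against a structure
#'
#' Selections use the grammar `a-b(,a-b)*` of 1-based inclusive C-alpha
#' index ranges in the renumbered convention (a bare `a` is shorthand for
#' `a-a`). Multi-range selections (e.g. a beta-sheet) are allowed;
#' overlapping ranges are merged with a warning; out-of-bounds indices
#' are an error.
#'
#' @param spec selection string, e.g. `"59-83"` or `"2-13,21-29"`.
#' @param structure a [CaStructure-class], [CaTrajectory-class], or a
#'   single integer giving the total C-alpha count.
#' @param name label for the resulting domain (defaults to `spec`).
#' @return a [DomainSelection-class].
#' @export
resolveSelection <- function(spec, structure, name = spec) {
    nCa <- if (is.numeric(structure)) as.integer(structure)
           else caCount(structure)
    parts <- strsplit(gsub("[[:space:]]", "", spec), ",", fixed = TRUE)[[1]]
    if (!length(parts)) stop("empty selection")
    idx <- integer(0)
    nDup <- 0L
    for (p in parts) {
        if (!grepl("^[0-9]+(-[0-9]+)?$", p))
            stop("selection token '", p, "' does not match a-b grammar")
        ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
        if (length(ab) == 1L) ab <- c(ab, ab)
        if (ab[1] > ab[2]) stop("range '", p, "' has a > b")
        r <- seq.int(ab[1], ab[2])
        nDup <- nDup + sum(r %in% idx)
        idx <- union(idx, r)
    }
    if (nDup > 0L)
        warning("overlapping ranges merged (", nDup, " duplicate indices)")
    if (max(idx) > nCa)
        stop("selection index ", max(idx), " out of bounds (", nCa,
             " C-alpha atoms)")
    new("DomainSelection", name = name, indices = sort(as.integer(idx)))
}
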