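## Packaged domain definitions of the modelled TCR/pMHC/CD8 complex.
## C-alpha index ranges follow the consecutive renumbering across the
## whole complex (chains concatenated A through G), as if the assembly
## came from a single PDB file.

.CHAIN_TABLE <- data.frame(
    name = c("MHC", "beta2-microglobulin", "peptide", "TCR alpha",
             "TCR beta", "CD8 alpha1", "CD8 alpha2"),
    chain = c("A", "B", "C", "D", "E", "F", "G"),
    printedLength = c(276L, 99L, 9L, 201L, 241L, 114L, 114L),
    ranges = c("1-276", "277-375", "376-384", "385-585", "586-826",
               "827-940", "941-1054"),
    stringsAsFactors = FALSE)

.SECONDARY_TABLE <- data.frame(
    name = c("Galpha1", "Galpha2", "alpha3", "beta-sheet",
             "TCR alpha var", "TCR beta var"),
    chain = c("A", "A", "A", "A", "D", "E"),
    printedLength = c(25L, 31L, 92L, 52L, 104L, 117L),
    ranges = c("59-83", "141-170", "184-275",
               "2-13,21-29,30-37,93-103,110-118,124-127",
               "385-488", "586-702"),
    stringsAsFactors = FALSE)

.rangeLength <- function(spec) {
    sum(vapply(strsplit(spec, ",")[[1]], function(p) {
        ab <- as.integer(strsplit(p, "-")[[1]])
        if (length(ab) == 1L) 1L else ab[2] - ab[1] + 1L
    }, integer(1)))
}

#' Domain definitions of the modelled TCR/pMHC/CD8 complex
#'
#' The packaged chain and secondary-structure table: C-alpha index ranges
#' (renumbered consecutively over the whole complex, chains A-G), the
#' published C-alpha counts, and the count computed from the inclusive
#' ranges. The ranges are stored verbatim; for two secondary-structure
#' rows the published count disagrees with the range arithmetic (Galpha2:
#' published 31 vs range 141-170 = 30; beta-sheet: published 52 vs ranges
#' summing to 53) and `lengthMatches` flags this. The computed length is
#' what [resolveSelection()] reports.
#'
#' @param what `"chains"`, `"secondary"`, or `"all"`.
#' @return data.frame with columns name, chain, printedLength, ranges,
#'   computedLength, lengthMatches.
#' @examples
#' tcrPmhcCd8Domains("secondary")
#' @export
tcrPmhcCd8Domains <- function(what = c("all", "chains", "secondary")) {
    what <- match.arg(what)
    tab <- switch(what,
        chains = .CHAIN_TABLE,
        secondary = .SECONDARY_TABLE,
        all = rbind(cbind(.CHAIN_TABLE, kind = "chain"),
                    cbind(.SECONDARY_TABLE, kind = "secondary")))
    tab$computedLength <- vapply(tab$ranges, .rangeLength, integer(1),
                                 USE.NAMES = FALSE)
    tab$lengthMatches <- tab$computedLength == tab$printedLength
    rownames(tab) <- NULL
    tab
}

#' Total C-alpha count of the modelled complex
#'
#' @param withCd8 include the CD8 chains F and G (default) or only the
#'   TCR/pMHC part (chains A-E).
#' @return integer C-alpha count (1054 with CD8, 836 without).
#' @export
complexCaCount <- function(withCd8 = TRUE) {
    tab <- tcrPmhcCd8Domains("chains")
    if (!withCd8) tab <- tab[tab$chain %in% c("A", "B", "C", "D", "E"), ]
    sum(tab$computedLength)
}

#' Resolve a packaged domain by name
#'
#' @param name row name from [tcrPmhcCd8Domains()], e.g. `"Galpha1"`.
#' @param nCa total C-alpha count to validate against (defaults to the
#'   full complex).
#' @return a [DomainSelection-class].
#' @export
complexDomain <- function(name, nCa = complexCaCount()) {
    tab <- tcrPmhcCd8Domains("all")
    i <- match(name, tab$name)
    if (is.na(i)) stop("unknown domain '", name, "'; see tcrPmhcCd8Domains()")
    resolveSelection(tab$ranges[i], nCa, name = name)
}
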