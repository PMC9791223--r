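#' Default serum sphingolipid species panel
#'
#' The panel covers the five serum sphingolipid classes measured by untargeted
#' lipidomics: dihydroceramides (DCER), ceramides (CER), sphingomyelins (SM),
#' hexosylceramides (HCER) and lactosylceramides (LCER). Species ids follow
#' the usual shorthand \code{<CLASS><chain carbons>[:<double bonds>]} for the
#' variable fatty-acid chain, e.g. \code{CER18}, \code{DCER22:2},
#' \code{LCER24:1}. The ceramide-pathway classes carry 4 DCER, 8 CER, 7 HCER
#' and 7 LCER species; the sphingomyelin count is configurable because SM
#' species are profiled but typically drop out of downstream network analyses.
#'
#' @param nSM number of sphingomyelin species to include (default 5)
#' @return data.frame with columns \code{species_id}, \code{class_id},
#'   \code{chain_carbons}, \code{double_bonds}
#' @examples
#' panel <- defaultSpeciesPanel()
#' table(panel$class_id)
#' @export
defaultSpeciesPanel <- function(nSM = 5) {
    stopifnot(nSM >= 0)
    species <- c(
        DCER = list(c("DCER18", "DCER22", "DCER22:2", "DCER24:1")),
        CER  = list(c("CER16", "CER18", "CER20", "CER22", "CER22:1",
                      "CER24", "CER24:1", "CER26")),
        HCER = list(c("HCER14", "HCER16", "HCER18", "HCER20", "HCER22",
                      "HCER22:1", "HCER24:1")),
        LCER = list(c("LCER14", "LCER16", "LCER18", "LCER18:1", "LCER20",
                      "LCER22:1", "LCER24:1")))
    smPool <- c("SM14", "SM16", "SM18", "SM20", "SM22", "SM24", "SM24:1",
                "SM26")
    if (nSM > length(smPool))
        stop("at most ", length(smPool), " SM species available")
    if (nSM > 0) species$SM <- smPool[seq_len(nSM)]
    ids <- unlist(species, use.names = FALSE)
    cls <- rep(names(species), lengths(species))
    chain <- as.integer(sub("^[A-Z]+(\\d+).*$", "\\1", ids))
    db <- rep(0L, length(ids))
    hasDB <- grepl(":", ids)
    db[hasDB] <- as.integer(sub("^.*:", "", ids[hasDB]))
    data.frame(species_id = ids, class_id = cls,
               chain_carbons = chain, double_bonds = db,
               stringsAsFactors = FALSE)
}

#' Names of the ceramide-pathway classes retained after volcano screening
#' @keywords internal
.coreClasses <- c("DCER", "CER", "HCER", "LCER")
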