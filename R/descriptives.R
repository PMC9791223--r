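#' Published descriptive counts of the MIDUS biomarker subsample
#'
#' Long-format counts of the MIDUS biomarker subsample by MetS status
#' (sociodemographics, nutritional status, exercise, smoking) plus the
#' enrollment/exclusion counts, as bundled with the package. Percentages in
#' published descriptive tables of this cohort are computed within variable
#' and group from exactly these counts.
#'
#' @return data.frame with columns \code{variable}, \code{level},
#'   \code{group}, \code{count}
#' @export
descriptiveCounts <- function() {
    utils::read.table(system.file("extdata", "midus_descriptive_counts.tsv",
                                  package = "sphingonet"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Percentage table from descriptive counts
#'
#' Converts long-format counts (\code{variable}, \code{level}, \code{group},
#' \code{count}) to percentages. With \code{margin = "group"} the
#' denominator is the sum of the displayed counts of the variable within
#' each group (the complete-case convention of descriptive cohort tables);
#' with \code{margin = "overall"} counts are first summed over groups and
#' the denominator is the variable total.
#'
#' @param counts data.frame as returned by \code{\link{descriptiveCounts}}
#' @param margin \code{"group"} or \code{"overall"}
#' @return the input with a \code{pct} column (unrounded percentages)
#' @examples
#' pt <- proportionTable(descriptiveCounts())
#' subset(pt, variable == "sex")
#' @export
proportionTable <- function(counts, margin = c("group", "overall")) {
    margin <- match.arg(margin)
    stopifnot(all(c("variable", "level", "group", "count") %in%
                  colnames(counts)))
    if (margin == "overall") {
        counts <- stats::aggregate(count ~ variable + level, counts, sum)
        counts$group <- "all"
    }
    key <- paste(counts$variable, counts$group)
    denom <- tapply(counts$count, key, sum)[key]
    counts$pct <- 100 * counts$count / as.numeric(denom)
    counts
}
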