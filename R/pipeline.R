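# Region-loop pipeline wrappers. These are the programmatic equivalents of
# the command-line subcommands; the shell script under inst/scripts/ is a
# thin optparse layer over them.

#' Deconvolve binding events across candidate regions
#'
#' Assigns reads to each candidate region (region extended by `flank` bp so
#' boundary events keep their informative fragments), selects the number of
#' events per region by BIC, and collects the event table. Regions with too
#' few reads are skipped with a warning and listed in the `skipped`
#' attribute.
#'
#' @param obs Tags (`mode = "set"`) or fragments (`mode = "pet"`).
#' @param regions Candidate regions `data.frame`.
#' @param mode `"pet"` or `"set"`.
#' @param G_max Maximum number of event components per region.
#' @param flank Assignment flank in bp; defaults to the maximum fragment
#'   length (PET) or 300 bp (SET).
#' @param min_reads Minimum observations required to fit a region.
#' @param ... Passed to [em_fit()] via [select_model()].
#' @return Event `data.frame` (see [events_from_fit()]) with attribute
#'   `skipped`.
#' @export
run_deconvolution <- function(obs, regions, mode = c("pet", "set"),
                              G_max = 5L, flank = NULL, min_reads = 10L,
                              ...) {
  mode <- match.arg(mode)
  if (is.null(flank)) {
    flank <- if (mode == "pet") max(obs$length) else 300L
  }
  events <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, , drop = FALSE]
    sub <- assign_to_region(obs, region, mode = mode, flank = flank)
    if (nrow(sub) < max(min_reads, 2L)) {
      warning("region ", region$region_id, " skipped: only ", nrow(sub),
              " reads")
      skipped <- c(skipped, region$region_id)
      next
    }
    fit <- tryCatch(select_model(sub, region, mode = mode, G_max = G_max, ...),
                    error = function(e) {
                      warning("region ", region$region_id, " skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) {
      skipped <- c(skipped, region$region_id)
      next
    }
    events[[length(events) + 1L]] <- events_from_fit(fit, region)
  }
  out <- if (length(events)) {
    do.call(rbind, events)
  } else {
    data.frame(region_id = character(0), chrom = character(0),
               position = integer(0), strength = numeric(0),
               weight = numeric(0), G_selected = integer(0),
               bic = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write a regions data.frame as BED
#'
#' @param regions Regions `data.frame`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  write.table(regions[, c("chrom", "start", "end", "region_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
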