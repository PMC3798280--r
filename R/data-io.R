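#' @importFrom stats dnorm pbinom ppois p.adjust quantile median runif rnorm sd qnorm aggregate binom.test
#' @importFrom utils read.table write.table
NULL

# Internal conventions
# --------------------
# Coordinates are 0-based inside the package. BED input/output is 0-based
# half-open; SAM is 1-based and converted on read. Event positions are
# reported 1-based in output tables.
#
# aligned tags   : data.frame(chrom, pos5, strand) with strand in {"+","-"}
#                  and pos5 the 5' end (0-based, inclusive).
# fragments      : data.frame(chrom, left, right, length), both ends 0-based
#                  inclusive, length = right - left + 1.
# regions        : data.frame(chrom, start, end, region_id), half-open.

.check_strand <- function(strand, line = NULL) {
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    where <- if (is.null(line)) which(bad)[1] else line[bad][1]
    stop("unknown strand symbol '", strand[bad][1], "' at line ", where)
  }
}

.read_bed_table <- function(path, min_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(list(tab = NULL, line_no = integer(0)))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    stop("malformed line ", which(nf < min_cols)[1], " in ", path,
         ": expected >= ", min_cols, " fields")
  }
  list(fields = fields, line_no = seq_along(lines))
}

#' Read single-end aligned tags
#'
#' Reads single-end (SET) reads from BED6 (or BED3, assumed forward strand)
#' or SAM and reduces each read to its 5' end plus strand: forward reads keep
#' the interval start, reverse reads the last covered base (interval end - 1
#' in 0-based coordinates). Unmapped and secondary SAM records are skipped
#' and their count reported via a message.
#'
#' @param path Path to the input file.
#' @param format `"bed"` or `"sam"`.
#' @return A `data.frame` with columns `chrom`, `pos5` (0-based) and
#'   `strand` (`"+"` / `"-"`).
#' @export
read_tags_set <- function(path, format = c("bed", "sam")) {
  format <- match.arg(format)
  if (format == "bed") {
    parsed <- .read_bed_table(path, min_cols = 3L)
    if (is.null(parsed$fields)) {
      return(data.frame(chrom = character(0), pos5 = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
    }
    chrom <- vapply(parsed$fields, `[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(parsed$fields, `[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(parsed$fields, `[`, "", 3L)))
    if (anyNA(start) || anyNA(end)) {
      stop("malformed line ", which(is.na(start) | is.na(end))[1], " in ", path)
    }
    strand <- vapply(parsed$fields, function(f) {
      if (length(f) >= 6L) f[6L] else "+"
    }, "")
    .check_strand(strand, parsed$line_no)
    pos5 <- ifelse(strand == "+", start, end - 1L)
    return(data.frame(chrom = chrom, pos5 = as.integer(pos5), strand = strand,
                      stringsAsFactors = FALSE))
  }
  sam <- .scan_sam(path)
  keep <- !bitwAnd(sam$flag, 4L) & !bitwAnd(sam$flag, 256L)
  n_skip <- sum(!keep)
  if (n_skip > 0) message("skipped ", n_skip, " unmapped/secondary records")
  rev <- bitwAnd(sam$flag[keep], 16L) > 0
  pos0 <- sam$pos[keep] - 1L
  width <- sam$qwidth[keep]
  data.frame(
    chrom = as.character(sam$rname[keep]),
    pos5 = as.integer(ifelse(rev, pos0 + width - 1L, pos0)),
    strand = ifelse(rev, "-", "+"),
    stringsAsFactors = FALSE
  )
}

.scan_sam <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth")
    )
  )[[1]]
  res
}

#' Read paired-end fragments
#'
#' Reads paired-end (PET) data either from a BEDPE-like file (chrom1 start1
#' end1 chrom2 start2 end2 [name]) or from a paired SAM file. Each mate pair
#' is collapsed to the DNA fragment it delimits: leftmost covered base to
#' rightmost covered base, inclusive. Pairs mapping to different chromosomes
#' are skipped and counted; SAM records whose mate is missing are skipped
#' with a warning.
#'
#' @param path Path to the input file.
#' @param format `"bedpe"` or `"sam"`.
#' @return A `data.frame` with columns `chrom`, `left`, `right` (0-based,
#'   inclusive) and `length`, with attribute `n_discordant`.
#' @export
read_fragments_pet <- function(path, format = c("bedpe", "sam")) {
  format <- match.arg(format)
  if (format == "bedpe") {
    parsed <- .read_bed_table(path, min_cols = 6L)
    if (is.null(parsed$fields)) {
      out <- data.frame(chrom = character(0), left = integer(0),
                        right = integer(0), length = integer(0),
                        stringsAsFactors = FALSE)
      attr(out, "n_discordant") <- 0L
      return(out)
    }
    get <- function(i) vapply(parsed$fields, `[`, "", i)
    chrom1 <- get(1L); chrom2 <- get(4L)
    s1 <- as.integer(get(2L)); e1 <- as.integer(get(3L))
    s2 <- as.integer(get(5L)); e2 <- as.integer(get(6L))
    concord <- chrom1 == chrom2
    n_disc <- sum(!concord)
    left <- pmin(s1, s2)[concord]
    right <- (pmax(e1, e2) - 1L)[concord]
    if (any(right < left)) {
      stop("negative fragment span at line ",
           parsed$line_no[concord][which(right < left)[1]])
    }
    out <- data.frame(chrom = chrom1[concord], left = left, right = right,
                      length = right - left + 1L, stringsAsFactors = FALSE)
    attr(out, "n_discordant") <- n_disc
    return(out)
  }
  sam <- .scan_sam_paired(path)
  sam
}

.scan_sam_paired <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth")
    )
  )[[1]]
  keep <- !bitwAnd(res$flag, 4L) & !bitwAnd(res$flag, 256L)
  qname <- res$qname[keep]
  chrom <- as.character(res$rname[keep])
  start0 <- res$pos[keep] - 1L
  end0 <- start0 + res$qwidth[keep] - 1L
  counts <- table(qname)
  paired <- names(counts)[counts == 2L]
  unpaired <- sum(counts != 2L)
  if (unpaired > 0) {
    warning("skipped ", unpaired, " read(s) without a usable mate")
  }
  idx <- qname %in% paired
  qn <- qname[idx]
  ord <- order(qn)
  qn <- qn[ord]
  chrom <- chrom[idx][ord]
  start0 <- start0[idx][ord]
  end0 <- end0[idx][ord]
  i1 <- seq(1L, length(qn), by = 2L)
  i2 <- i1 + 1L
  concord <- chrom[i1] == chrom[i2]
  n_disc <- sum(!concord)
  left <- pmin(start0[i1], start0[i2])[concord]
  right <- pmax(end0[i1], end0[i2])[concord]
  out <- data.frame(chrom = chrom[i1][concord], left = left, right = right,
                    length = right - left + 1L, stringsAsFactors = FALSE)
  attr(out, "n_discordant") <- n_disc
  out
}

#' Read candidate regions from BED
#'
#' Candidate peak regions are BED3+ intervals; a fourth column, when present,
#' supplies the region identifier, otherwise identifiers `region_0001`, ...
#' are generated. Input order is preserved and overlapping regions are not
#' merged.
#'
#' @param path Path to a BED3+ file.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `region_id`.
#' @export
read_regions_bed <- function(path) {
  parsed <- .read_bed_table(path, min_cols = 3L)
  if (is.null(parsed$fields)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_id = character(0),
                      stringsAsFactors = FALSE))
  }
  chrom <- vapply(parsed$fields, `[`, "", 1L)
  start <- as.integer(vapply(parsed$fields, `[`, "", 2L))
  end <- as.integer(vapply(parsed$fields, `[`, "", 3L))
  bad <- end <= start
  if (any(bad)) {
    stop("region end <= start at line ", parsed$line_no[bad][1], " in ", path)
  }
  ids <- vapply(seq_along(parsed$fields), function(i) {
    f <- parsed$fields[[i]]
    if (length(f) >= 4L && nzchar(f[4L])) f[4L] else sprintf("region_%04d", i)
  }, "")
  data.frame(chrom = chrom, start = start, end = end, region_id = ids,
             stringsAsFactors = FALSE)
}

#' Construct a fragment-length distribution
#'
#' A discrete probability mass function over fragment (library) sizes in bp.
#'
#' @param support Integer vector of distinct lengths (bp), all >= 1.
#' @param pmf Numeric vector of probabilities, same length as `support`.
#' @return An object of class `"fld"`: a list with sorted `support` and
#'   `pmf` summing to one.
#' @export
fragment_length_dist <- function(support, pmf) {
  stopifnot(length(support) == length(pmf), length(support) >= 1)
  if (any(support < 1)) stop("fragment lengths must be >= 1")
  if (any(pmf < 0)) stop("probabilities must be non-negative")
  s <- sum(pmf)
  if (s <= 0) stop("probabilities sum to zero")
  ord <- order(support)
  support <- as.integer(support[ord])
  pmf <- unname(pmf[ord] / s)
  if (anyDuplicated(support)) stop("support values must be distinct")
  structure(list(support = support, pmf = pmf), class = "fld")
}

#' @export
print.fld <- function(x, ...) {
  m <- sum(x$support * x$pmf)
  v <- sum(x$support^2 * x$pmf) - m^2
  cat("fragment-length distribution: ", length(x$support),
      " lengths in [", min(x$support), ", ", max(x$support), "] bp, mean ",
      round(m, 1), " bp, sd ", round(sqrt(max(v, 0)), 1), " bp\n", sep = "")
  invisible(x)
}

#' Empirical fragment-length distribution from PET fragments
#'
#' Tabulates observed fragment lengths restricted to a plausible window and
#' normalizes to a probability mass function. The window default brackets
#' typical sonication sizes.
#'
#' @param fragments Fragment `data.frame` (see [read_fragments_pet()]).
#' @param min_len,max_len Window of admissible lengths (bp).
#' @return An `"fld"` object.
#' @export
estimate_length_distribution <- function(fragments, min_len = 50L,
                                         max_len = 500L) {
  len <- fragments$length
  len <- len[len >= min_len & len <= max_len]
  if (length(len) == 0L) {
    stop("no fragment with length in [", min_len, ", ", max_len, "]")
  }
  tab <- table(len)
  fragment_length_dist(as.integer(names(tab)), as.numeric(tab))
}

.fld_mean <- function(fld) sum(fld$support * fld$pmf)
.fld_sd <- function(fld) {
  m <- .fld_mean(fld)
  sqrt(max(sum(fld$support^2 * fld$pmf) - m^2, 0))
}

.sample_lengths <- function(fld, n) {
  if (length(fld$support) == 1L) {
    rep(fld$support, n)
  } else {
    sample(fld$support, n, replace = TRUE, prob = fld$pmf)
  }
}

#' Assign reads to candidate regions
#'
#' Reads are attached to a region if informative for events inside it: a SET
#' tag qualifies when its 5' end falls inside the region extended by `flank`
#' on both sides; a PET fragment when it overlaps the extended region. The
#' flank accounts for fragments that start outside the region but cover an
#' event near its boundary; `flank` defaults to the maximum library size
#' when a length distribution is given.
#'
#' @param obs Tags or fragments `data.frame`.
#' @param region One row of a regions `data.frame`.
#' @param mode `"set"` or `"pet"`.
#' @param flank Extension in bp (default 0).
#' @return The subset of `obs` assigned to `region`.
#' @export
assign_to_region <- function(obs, region, mode = c("set", "pet"), flank = 0L) {
  mode <- match.arg(mode)
  lo <- region$start - flank
  hi <- region$end + flank        # half-open upper bound
  if (mode == "set") {
    keep <- obs$chrom == region$chrom & obs$pos5 >= lo & obs$pos5 < hi
  } else {
    keep <- obs$chrom == region$chrom & obs$right >= lo & obs$left < hi
  }
  obs[keep, , drop = FALSE]
}

#' Write predicted events
#'
#' Writes one row per predicted binding event: region identifier, chromosome,
#' 1-based position, strength (mixture weight times region read count),
#' relative weight, selected number of events and the model's BIC. A
#' companion BED file of 1-bp point intervals is written alongside.
#'
#' @param events Event table as returned by [run_deconvolution()] (internal
#'   0-based `position` column).
#' @param path Output TSV path.
#' @param bed_path Companion BED path (default `paste0(path, ".bed")`).
#' @export
write_events <- function(events, path, bed_path = paste0(path, ".bed")) {
  cols <- c("region_id", "chrom", "position", "strength", "weight",
            "G_selected", "bic")
  out <- events[, cols, drop = FALSE]
  out$position <- out$position + 1L   # report 1-based
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  close(con)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(events) > 0L) {
    bed <- data.frame(chrom = events$chrom, start = events$position,
                      end = events$position + 1L, name = events$region_id,
                      score = round(events$strength, 2), strand = ".")
    write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    writeLines(character(0), bed_path)
  }
  invisible(path)
}

#' Write tags / fragments in BED dialects
#'
#' Helpers used by the simulator so simulated data round-trips through the
#' same readers as experimental data. Tags are written as BED6 intervals of
#' `width` bp anchored at the 5' end; fragments as BEDPE-like records split
#' into two `width`-bp mate intervals.
#'
#' @param tags,fragments Data frames in internal representation.
#' @param path Output path.
#' @param width Nominal read width in bp.
#' @rdname write_reads
#' @export
write_tags_bed <- function(tags, path, width = 32L) {
  start <- ifelse(tags$strand == "+", tags$pos5, tags$pos5 - width + 1L)
  start <- pmax(start, 0L)
  end <- ifelse(tags$strand == "+", tags$pos5 + width, tags$pos5 + 1L)
  df <- data.frame(tags$chrom, start, end,
                   sprintf("tag_%d", seq_len(nrow(tags))), 0L, tags$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_reads
#' @export
write_fragments_bedpe <- function(fragments, path, width = 36L) {
  w <- pmin(width, fragments$length)
  df <- data.frame(fragments$chrom, fragments$left, fragments$left + w,
                   fragments$chrom, fragments$right - w + 1L,
                   fragments$right + 1L,
                   sprintf("frag_%d", seq_len(nrow(fragments))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
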