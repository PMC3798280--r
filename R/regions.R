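# Lightweight candidate-region detection by windowed testing. Stands in for
# a full peak caller: the deconvolution step only needs approximate peak
# intervals, and users with MOSAiCS/MACS output can pass it straight through
# read_regions_bed().

#' Conditional binomial enrichment p-value
#'
#' For a window with `x` ChIP reads and `y` control reads, conditions on the
#' combined count: under no enrichment, `X ~ Binomial(x + y, t)` where `t`
#' is the ChIP share of total sequencing depth. Returns the upper tail
#' `P(X >= x)`.
#'
#' @param x ChIP read count(s).
#' @param y Control read count(s).
#' @param t ChIP depth fraction, `chip_total / (chip_total + control_total)`,
#'   strictly in (0, 1).
#' @return Upper-tail p-value(s); 1 where `x + y = 0`.
#' @export
conditional_binomial_pvalue <- function(x, y, t) {
  if (t <= 0 || t >= 1) stop("t must be in (0, 1)")
  n <- x + y
  p <- pbinom(x - 1, n, t, lower.tail = FALSE)
  p[n == 0] <- 1
  p
}

#' Benjamini-Hochberg step-up correction
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")` that also returns
#' rejection flags at a target FDR.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param alpha Target false discovery rate.
#' @return A list with `adjusted` p-values and logical `reject` flags.
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Call candidate regions from windowed read counts
#'
#' Tiles the observed read span of each chromosome into non-overlapping
#' windows, counts 5' ends per window, tests each non-empty window for
#' enrichment, applies Benjamini-Hochberg across the tested windows, and
#' merges significant windows separated by at most `gap` bp into candidate
#' regions. With a control sample the test is the conditional binomial; in
#' one-sample mode each window count is tested against the genome-wide mean
#' Poisson rate.
#'
#' Windows with zero combined count carry no evidence and are excluded from
#' the multiple-testing family.
#'
#' @param chip Tags `data.frame` for the ChIP sample.
#' @param control Optional tags `data.frame` for the input/control sample
#'   (`NULL` for one-sample mode).
#' @param window Window width in bp.
#' @param gap Maximum separation for merging significant windows (bp).
#' @param alpha Target FDR.
#' @return A regions `data.frame` (`chrom`, `start`, `end`, `region_id`).
#' @export
call_candidate_regions <- function(chip, control = NULL, window = 50L,
                                   gap = 100L, alpha = 0.05) {
  stopifnot(window >= 1)
  if (nrow(chip) == 0L) stop("no reads supplied")
  two_sample <- !is.null(control) && nrow(control) > 0L
  out <- list()
  for (chr in unique(chip$chrom)) {
    cpos <- chip$pos5[chip$chrom == chr]
    ypos <- if (two_sample) control$pos5[control$chrom == chr] else integer(0)
    span_lo <- min(cpos, ypos)
    span_hi <- max(cpos, ypos) + 1L
    breaks <- seq(span_lo, span_hi + window, by = window)
    wstart <- breaks[-length(breaks)]
    xcnt <- tabulate(findInterval(cpos, breaks), nbins = length(wstart))
    ycnt <- if (two_sample) {
      tabulate(findInterval(ypos, breaks), nbins = length(wstart))
    } else {
      integer(length(wstart))
    }
    tested <- xcnt + ycnt > 0
    if (!any(tested)) next
    if (two_sample) {
      t_ratio <- length(cpos) / (length(cpos) + length(ypos))
      pv <- conditional_binomial_pvalue(xcnt[tested], ycnt[tested], t_ratio)
    } else {
      rate <- length(cpos) / length(wstart)   # mean reads per window
      pv <- ppois(xcnt[tested] - 1, rate, lower.tail = FALSE)
    }
    rej <- bh_adjust(pv, alpha)$reject
    sig_start <- wstart[tested][rej]
    if (length(sig_start) == 0L) next
    sig_start <- sort(sig_start)
    sig_end <- sig_start + window
    # merge windows separated by <= gap
    new_block <- c(TRUE, sig_start[-1] - sig_end[-length(sig_end)] > gap)
    block <- cumsum(new_block)
    out[[chr]] <- data.frame(
      chrom = chr,
      start = as.integer(tapply(sig_start, block, min)),
      end = as.integer(tapply(sig_end, block, max)),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_id = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$region_id <- sprintf("region_%04d", seq_len(nrow(res)))
  res
}
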