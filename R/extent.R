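## Methylation-extent categorization: chi-square comparison of MFPKM vs FPKM
## per transcript (High / Low / Equivalent), expression-tertile grouping
## summaries, and the extensively-methylated filter.

#' Chi-square on the MFPKM:FPKM balance
#'
#' Two-cell goodness-of-fit of the percentage split of the two values against
#' 50:50:
#' \deqn{\chi^2 = (100 a/(a+b) - 50)^2/50 + (100 b/(a+b) - 50)^2/50}
#' The p-value is the upper tail of the chi-square distribution with 1 df
#' (two cells, one free proportion). The same statistic drives the
#' between-organ differential tests.
#'
#' @param mfpkm,fpkm non-negative values (vectorized); their sum must be > 0.
#' @return data.frame with \code{chi2} and \code{p_value}.
#' @export
ratio_chi_square <- function(mfpkm, fpkm) {
  if (any(mfpkm + fpkm <= 0)) stop("both values zero")
  if (any(mfpkm < 0 | fpkm < 0)) stop("negative value")
  pa <- mfpkm * 100 / (mfpkm + fpkm)
  chi2 <- (pa - 50)^2 / 50 + ((100 - pa) - 50)^2 / 50
  data.frame(chi2 = chi2,
             p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Classify methylation extent per transcript
#'
#' Methylated transcripts (m6a_count > 0) are categorized \code{High} when
#' the chi-square test rejects the 1:1 MFPKM:FPKM balance (p < alpha) with
#' MFPKM > FPKM, \code{Low} when it rejects with MFPKM < FPKM, and
#' \code{Equivalent} otherwise (p >= alpha). Unmethylated transcripts are
#' excluded. FDR (Benjamini-Hochberg) is computed within organ/replicate for
#' downstream filtering.
#'
#' @param quant output of \code{\link{quantify}} (one or more
#'   organ/replicates).
#' @param alpha significance level (default 0.05).
#' @return data.frame of extent calls, carrying the quantification columns.
#' @export
classify_extent <- function(quant, alpha = 0.05) {
  calls <- quant[quant$m6a_count > 0, , drop = FALSE]
  if (nrow(calls) == 0)
    stop("no methylated transcripts to classify")
  cs <- ratio_chi_square(calls$mfpkm, calls$fpkm)
  calls$chi2 <- cs$chi2
  calls$p_value <- cs$p_value
  calls$category <- ifelse(calls$p_value >= alpha, "Equivalent",
                           ifelse(calls$mfpkm > calls$fpkm, "High", "Low"))
  grp <- paste(calls$organ, calls$replicate)
  calls$fdr <- stats::ave(calls$p_value, grp,
                          FUN = function(p) stats::p.adjust(p, method = "fdr"))
  rownames(calls) <- NULL
  calls
}

#' Category percentages from extent-category counts
#'
#' The arithmetic behind the published three-grouping tables: percentage =
#' count / total categorized x 100 at 1-decimal rounding, and per-replicate
#' cross-organ averages (unweighted mean of the per-organ percentages).
#'
#' @param counts data.frame with columns \code{organ}, \code{replicate},
#'   \code{high}, \code{low}, \code{equivalent} (counts).
#' @return \code{counts} with \code{high_pct}, \code{low_pct},
#'   \code{equivalent_pct} appended, plus one \code{"average"} row per
#'   replicate.
#' @export
extent_percentages <- function(counts) {
  stopifnot(all(c("organ", "replicate", "high", "low", "equivalent")
                %in% names(counts)))
  total <- counts$high + counts$low + counts$equivalent
  counts$high_pct <- round(counts$high / total * 100, 1)
  counts$low_pct <- round(counts$low / total * 100, 1)
  counts$equivalent_pct <- round(counts$equivalent / total * 100, 1)
  avg <- do.call(rbind, lapply(split(counts, counts$replicate), function(d)
    data.frame(organ = "average", replicate = d$replicate[1],
               high = NA, low = NA, equivalent = NA,
               high_pct = round(mean(d$high_pct), 1),
               low_pct = round(mean(d$low_pct), 1),
               equivalent_pct = round(mean(d$equivalent_pct), 1))))
  out <- rbind(counts, avg)
  rownames(out) <- NULL
  out
}

#' Tabulate extent categories per organ/replicate
#'
#' @param calls output of \code{\link{classify_extent}}.
#' @return see \code{\link{extent_percentages}}.
#' @export
tabulate_extent <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  tab <- as.data.frame(table(organ = calls$organ,
                             replicate = calls$replicate,
                             category = calls$category))
  counts <- stats::reshape(tab, idvar = c("organ", "replicate"),
                           timevar = "category", direction = "wide")
  names(counts) <- sub("^Freq\\.", "", names(counts))
  for (cat in c("High", "Low", "Equivalent"))
    if (!cat %in% names(counts)) counts[[cat]] <- 0L
  counts <- data.frame(organ = as.character(counts$organ),
                       replicate = as.integer(as.character(counts$replicate)),
                       high = counts$High, low = counts$Low,
                       equivalent = counts$Equivalent)
  counts <- counts[counts$high + counts$low + counts$equivalent > 0, ]
  extent_percentages(counts)
}

#' Expression-tertile grouping summary
#'
#' Methylated transcripts are ranked by FPKM (descending, ties broken by
#' transcript id) and split into thirds (remainder to earlier groups). Each
#' grouping reports mean MFPKM, mean FPKM and their ratio; pairwise Welch
#' t-tests compare the per-transcript MFPKM/FPKM ratios between groupings.
#'
#' @param quant output of \code{\link{quantify}} for one organ/replicate.
#' @return list with \code{groups} (grouping, n, mean_mfpkm, mean_fpkm,
#'   ratio) and \code{t_tests} (grouping pair, p_value; \code{NA} when a
#'   grouping's ratios are degenerate).
#' @export
grouping_summary <- function(quant) {
  q <- quant[quant$m6a_count > 0, , drop = FALSE]
  if (nrow(q) < 3) stop("need at least 3 methylated transcripts")
  q <- q[order(-q$fpkm, q$transcript_id), ]
  n <- nrow(q)
  sizes <- rep(n %/% 3, 3) + (1:3 <= n %% 3)
  grouping <- rep(c("High", "Moderate", "Low"), times = sizes)
  q$ratio <- q$mfpkm / ifelse(q$fpkm > 0, q$fpkm, NA)
  groups <- do.call(rbind, lapply(split(q, grouping)[c("High", "Moderate", "Low")],
    function(d) data.frame(n = nrow(d),
                           mean_mfpkm = mean(d$mfpkm),
                           mean_fpkm = mean(d$fpkm),
                           ratio = mean(d$mfpkm) / mean(d$fpkm))))
  groups <- cbind(grouping = rownames(groups), groups)
  rownames(groups) <- NULL
  pairs <- utils::combn(c("High", "Moderate", "Low"), 2)
  tt <- apply(pairs, 2, function(pr) {
    a <- q$ratio[grouping == pr[1]]
    b <- q$ratio[grouping == pr[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
      return(NA_real_)
    stats::t.test(a, b)$p.value
  })
  list(groups = groups,
       t_tests = data.frame(grouping_a = pairs[1, ], grouping_b = pairs[2, ],
                            p_value = tt))
}

#' Call extensively methylated transcripts
#'
#' Per organ: transcripts with MFPKM:FPKM fold >= \code{fold},
#' FDR < \code{fdr_max} and m6A fragment count >= \code{min_reads}, in every
#' replicate (common-elements rule).
#'
#' @param calls output of \code{\link{classify_extent}} (all organs and
#'   replicates to consider).
#' @param fold minimum MFPKM:FPKM ratio (default 10).
#' @param fdr_max FDR ceiling (default 1e-12).
#' @param min_reads minimum m6A fragments per transcript (default 30).
#' @return named list (per organ) of transcript id vectors.
#' @export
call_extensively_methylated <- function(calls, fold = 10, fdr_max = 1e-12,
                                        min_reads = 30) {
  pass <- calls$mfpkm >= fold * calls$fpkm &
    calls$fdr < fdr_max & calls$m6a_count >= min_reads
  organs <- unique(calls$organ)
  out <- lapply(organs, function(o) {
    reps <- unique(calls$replicate[calls$organ == o])
    per_rep <- lapply(reps, function(r) {
      d <- calls[pass & calls$organ == o & calls$replicate == r, ]
      d$transcript_id
    })
    Reduce(intersect, per_rep)
  })
  names(out) <- organs
  out
}

#' Intersect per-organ transcript sets
#' @param sets list of character vectors (e.g. from
#'   \code{\link{call_extensively_methylated}}).
#' @return transcript ids common to all sets.
#' @export
intersect_organs <- function(sets) {
  Reduce(intersect, sets)
}
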