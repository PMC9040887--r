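# Per-genome copy-number census, copy-number frequency spectra, YQL/AZL
# coincidence, and pairwise one-way ANOVA of copy counts across subfamilies.

#' Per-genome subfamily copy-number census
#'
#' Counts classified calls per genome and subfamily; UNCLASSIFIED calls are
#' not counted, so the grand total equals the number of classified calls.
#'
#' @param calls `data.frame` with columns `genome_id` and `subfamily`
#'   (typically the `calls` element of [classify_proteome()] joined to a
#'   genome map, or a generator manifest).
#' @return `data.frame` with columns `genome_id`, `YQL`, `AZL`, `AZL2`
#'   (non-negative integer copy counts; one row per genome present in
#'   `calls`).
#' @export
census <- function(calls) {
  if (nrow(calls) == 0)
    return(data.frame(genome_id = character(), YQL = integer(),
                      AZL = integer(), AZL2 = integer()))
  genomes <- unique(calls$genome_id)
  m <- sapply(SUBFAMILIES, function(sf)
    vapply(genomes, function(g)
      sum(calls$genome_id == g & calls$subfamily == sf), integer(1)))
  m <- matrix(m, nrow = length(genomes),
              dimnames = list(genomes, SUBFAMILIES))
  out <- data.frame(genome_id = genomes, m, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Copy-number frequency spectrum for one subfamily
#'
#' Percentage of genomes carrying 1, 2, 3, 4 or >=5 copies. By default the
#' denominator is genomes carrying at least one copy of the subfamily;
#' `include_zero = TRUE` switches to all genomes (adding a `0` bin).
#'
#' @param censuses output of [census()].
#' @param subfamily one of `"YQL"`, `"AZL"`, `"AZL2"`.
#' @param include_zero include zero-copy genomes in the denominator.
#' @param max_bin copies at or above this value are binned together
#'   (default 5).
#' @return `data.frame` with columns `copies` (character; `"5+"` for the top
#'   bin), `n_genomes`, `percent`; percentages sum to 100. Zero rows when the
#'   subfamily is absent everywhere and `include_zero` is `FALSE`.
#' @export
copy_number_frequency <- function(censuses, subfamily,
                                  include_zero = FALSE, max_bin = 5L) {
  stopifnot(subfamily %in% SUBFAMILIES)
  cnt <- censuses[[subfamily]]
  if (!include_zero) cnt <- cnt[cnt >= 1L]
  if (!length(cnt))
    return(data.frame(copies = character(), n_genomes = integer(),
                      percent = numeric()))
  binned <- pmin(cnt, max_bin)
  labs <- c(if (include_zero) "0", as.character(seq_len(max_bin - 1L)),
            paste0(max_bin, "+"))
  vals <- c(if (include_zero) 0L, seq_len(max_bin))
  tab <- table(factor(binned, levels = vals))
  data.frame(copies = labs, n_genomes = as.integer(tab),
             percent = 100 * as.integer(tab) / length(cnt),
             stringsAsFactors = FALSE)
}

#' YQL/AZL coincidence table
#'
#' Cross-tabulates per-genome YQL and AZL copy numbers and totals the genomes
#' carrying both subfamilies, exactly one, or neither. Cells partition the
#' genome set.
#'
#' @param censuses output of [census()].
#' @return list with `cells` (`data.frame`: `yql_count`, `azl_count`,
#'   `n_genomes`) and `totals` (named vector: `both`, `either_only`,
#'   `neither`).
#' @export
coincidence <- function(censuses) {
  y <- censuses$YQL; a <- censuses$AZL
  key <- paste(y, a, sep = ":")
  tab <- table(key)
  parts <- strsplit(names(tab), ":", fixed = TRUE)
  cells <- data.frame(
    yql_count = as.integer(vapply(parts, `[`, "", 1L)),
    azl_count = as.integer(vapply(parts, `[`, "", 2L)),
    n_genomes = as.integer(tab))
  cells <- cells[order(cells$yql_count, cells$azl_count), , drop = FALSE]
  rownames(cells) <- NULL
  totals <- c(both = sum(y > 0 & a > 0),
              either_only = sum(xor(y > 0, a > 0)),
              neither = sum(y == 0 & a == 0))
  list(cells = cells, totals = totals)
}

#' Pairwise one-way ANOVA of copy counts
#'
#' Classical one-way fixed-effects ANOVA of two groups of per-genome copy
#' counts. With two groups, F equals the square of the pooled two-sample
#' t statistic.
#'
#' @param counts_a,counts_b integer vectors (each length >= 2).
#' @return list with `F`, `df` (numerator, denominator) and `p_value`.
#' @export
anova_pairwise <- function(counts_a, counts_b) {
  if (length(counts_a) < 2L || length(counts_b) < 2L)
    stop("each group needs at least 2 values")
  y <- c(counts_a, counts_b)
  g <- factor(rep(c("a", "b"), c(length(counts_a), length(counts_b))))
  if (stats::var(y) == 0)
    stop("degenerate ANOVA: zero variance in both groups with equal means")
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], df = c(s$Df[1], s$Df[2]),
       p_value = s$`Pr(>F)`[1])
}
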