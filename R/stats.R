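#' Scaffold N50 from a list of spans
#'
#' Spans are sorted in decreasing order and the N50 is the span at which
#' the cumulative sum first reaches at least half of the total span.
#' Singleton contigs count as one-contig scaffolds, so the denominator is
#' the total scaffold span of the assembly.
#'
#' @param spans Numeric vector of scaffold spans in bp; must be non-empty
#'   and positive.
#' @return The N50 span in bp.
#' @export
n50 <- function(spans) {
  if (length(spans) == 0) stop("n50 of an empty span list is undefined")
  if (any(spans <= 0)) stop("spans must be positive")
  s <- sort(spans, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Summarise an assembly the way scaffolder reports do
#'
#' @param scaffold_set Result of [greedy_scaffold()] (or any list with a
#'   `scaffolds` data.frame carrying `n_contigs` and `span`).
#' @param n_initial_contigs Number of contigs the scaffolder started from.
#' @param n_pairs_used Number of (pseudo) read pairs that produced links.
#' @return One-row data.frame: `n_pairs_used`, `total_span`, `n50_span`,
#'   `n_scaffolds` (singletons included), `pct_contigs_scaffolded`
#'   (percentage of initial contigs sitting in scaffolds of >= 2 contigs,
#'   to 1 decimal).
#' @export
summarize_assembly <- function(scaffold_set, n_initial_contigs,
                               n_pairs_used = NA_integer_) {
  if (n_initial_contigs <= 0) stop("n_initial_contigs must be positive")
  sc <- scaffold_set$scaffolds
  in_multi <- sum(sc$n_contigs[sc$n_contigs >= 2])
  data.frame(
    n_pairs_used = n_pairs_used,
    total_span = sum(sc$span),
    n50_span = n50(sc$span),
    n_scaffolds = nrow(sc),
    pct_contigs_scaffolded = round(100 * in_multi / n_initial_contigs, 1),
    stringsAsFactors = FALSE
  )
}

#' Read a scaffold layout back from an AGP file
#'
#' Consumes AGP v2.0 as written by [write_agp()] (W component rows and N
#' gap rows) and rebuilds the per-scaffold placements, e.g. to compute
#' statistics on a layout produced in an earlier run.
#'
#' @param path AGP file path.
#' @return A `scaffold_set`-shaped list with `placements` and `scaffolds`
#'   (no conflict report).
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  comp <- f[vapply(f, `[`, "", 5) == "W"]
  pl <- data.frame(
    scaffold_id = vapply(comp, `[`, "", 1),
    contig_id = vapply(comp, `[`, "", 6),
    offset = as.numeric(vapply(comp, `[`, "", 2)) - 1,
    orientation = vapply(comp, `[`, "", 9),
    contig_len = as.numeric(vapply(comp, `[`, "", 8)),
    stringsAsFactors = FALSE
  )
  pl$gap_after <- NA_real_
  for (sid in unique(pl$scaffold_id)) {
    ix <- which(pl$scaffold_id == sid)
    if (length(ix) > 1) {
      o <- pl$offset[ix]
      pl$gap_after[ix[-length(ix)]] <-
        o[-1] - (o[-length(o)] + pl$contig_len[ix[-length(ix)]])
    }
  }
  span <- tapply(pl$offset + pl$contig_len, pl$scaffold_id, max)
  sc <- data.frame(scaffold_id = names(span),
                   n_contigs = as.integer(table(pl$scaffold_id)[names(span)]),
                   span = as.numeric(span), stringsAsFactors = FALSE)
  rownames(sc) <- NULL
  list(placements = pl, scaffolds = sc)
}
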