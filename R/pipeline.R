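#' Run the full link-combine-scaffold pipeline on a fixture directory
#'
#' Convenience driver over the module functions, wired the way the
#' original wallaby pipeline was: marker map + PSL placements become
#' pseudo mate-pair links in distance-binned libraries (priority 2), SAM
#' read pairs become sequence links (priority 1), both link sets are
#' bundled together and scaffolded greedily with sequence evidence
#' consumed first, so it overrides map evidence on conflict.
#'
#' @param dir Directory laid out like [simulate_fixture()] output:
#'   `contigs.fa`, and optionally `map.tsv` + `markers.psl`, and
#'   `libraries.tsv` + `lib_<name>.sam` files.
#' @param use_map,use_seq Switch either data type off to reproduce the
#'   map-only / sequence-only runs.
#' @param d_start,d_end,d_step Pseudo-library distance grid (bp).
#' @param max_mismatches Per-mate mismatch cap for SAM pairs.
#' @param min_weight Minimum bundle weight by priority
#'   (see [bundle_links()]).
#' @return List: `scaffolds` (a `scaffold_set`), `stats` (one-row summary,
#'   see [summarize_assembly()]), `links`, `skips` (per-source skip
#'   tallies), `libraries`, `contig_lengths`.
#' @export
scaffold_fixture <- function(dir, use_map = TRUE, use_seq = TRUE,
                             d_start = 5e6, d_end = 10e6, d_step = 1e6,
                             max_mismatches = 3L,
                             min_weight = c("1" = 2, "2" = 1)) {
  fa <- file.path(dir, "contigs.fa")
  if (!file.exists(fa)) stop("no contigs.fa under ", dir)
  contig_lengths <- Biostrings::fasta.seqlengths(fa)
  link_sets <- list(); skips <- list(); libs <- list()

  if (use_seq) {
    lib_tab <- as.data.frame(data.table::fread(file.path(dir, "libraries.tsv")))
    for (i in seq_len(nrow(lib_tab))) {
      spec <- make_seq_library(lib_tab$name[i], lib_tab$insert_mean[i])
      sam <- file.path(dir, paste0("lib_", lib_tab$name[i], ".sam"))
      got <- parse_sam_pairs(sam, spec, max_mismatches = max_mismatches)
      link_sets[[spec$name]] <- got$links
      skips[[spec$name]] <- got$skips
      libs[[spec$name]] <- spec
    }
  }
  if (use_map) {
    markers <- parse_map_table(file.path(dir, "map.tsv"))
    placements <- load_placements(file.path(dir, "markers.psl"))
    map_libs <- make_pseudo_libraries(d_start, d_end, d_step, priority = 2L)
    pairs <- enumerate_pseudo_pairs(markers, map_libs)
    got <- pairs_to_links(pairs, placements, map_libs, contig_lengths)
    link_sets[["map"]] <- got$links
    skips[["map"]] <- got$skips
    libs[["map"]] <- map_libs
  }
  links <- do.call(rbind, c(link_sets, list(make.row.names = FALSE)))
  if (is.null(links)) links <- .empty_links()
  bundles <- bundle_links(links, min_weight = min_weight)
  scaffolds <- greedy_scaffold(bundles, contig_lengths)
  stats <- summarize_assembly(scaffolds,
                              n_initial_contigs = length(contig_lengths),
                              n_pairs_used = nrow(links))
  list(scaffolds = scaffolds, stats = stats, links = links, skips = skips,
       libraries = do.call(rbind, c(libs, list(make.row.names = FALSE))),
       contig_lengths = contig_lengths)
}

#' Read contig lengths from FASTA or a two-column TSV
#'
#' @param path `.fa`/`.fasta` file, or a TSV with columns
#'   `contig_id`, `length` (header optional).
#' @return Named numeric vector of lengths.
#' @export
read_contig_lengths <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) > 0 && startsWith(first, ">"))
    return(Biostrings::fasta.seqlengths(path))
  tab <- as.data.frame(data.table::fread(path, header = "auto"))
  if (ncol(tab) < 2) stop("contig length TSV needs two columns")
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}
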