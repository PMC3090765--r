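#' Write a Bambus-style mates file
#'
#' Emits the legacy two-part grammar: one `library <name> <min> <max>` line
#' per library, then one `<read1> <read2> <library>` line per pair, both
#' blocks in lexicographic order so repeated runs are byte-identical.
#' Best-effort interoperability output; validated by round-trip, not
#' against the original binary.
#'
#' @param links Link data.frame (needs `read_a`, `read_b`, `library`).
#' @param libraries Library spec data.frame; every link's library must
#'   appear in it.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bambus_mates <- function(links, libraries, path) {
  unknown <- setdiff(unique(links$library), libraries$name)
  if (length(unknown) > 0)
    stop("link references unknown library: ", unknown[1])
  lb <- libraries[order(libraries$name), ]
  lib_lines <- sprintf("library %s %d %d", lb$name,
                       as.integer(lb$insert_min), as.integer(lb$insert_max))
  pair_lines <- character(0)
  if (nrow(links) > 0) {
    pair_lines <- sprintf("%s %s %s", links$read_a, links$read_b,
                          links$library)
    pair_lines <- sort(pair_lines)
  }
  writeLines(c(lib_lines, pair_lines), path)
  invisible(path)
}

#' Write a Bambus-style contig file
#'
#' TIGR .contig-flavoured records: a `##` header line per contig followed
#' by one `#` line per read placed on it, giving the read's offset and
#' orientation (`RC` marks a reverse-complement placement). Ordering is
#' lexicographic throughout (contigs, then reads) for determinism.
#'
#' @param reads Data.frame with columns `read_id`, `contig_id`, `offset`
#'   (0-based bp on the contig), `length` (read/marker footprint in bp) and
#'   `orientation` (`+`/`-`).
#' @param contig_lengths Named numeric vector; every read's contig must be
#'   present.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bambus_contig <- function(reads, contig_lengths, path) {
  if (nrow(reads) > 0) {
    unknown <- setdiff(unique(reads$contig_id), names(contig_lengths))
    if (length(unknown) > 0)
      stop("read placed on unknown contig: ", unknown[1])
  }
  lines <- character(0)
  for (ctg in sort(unique(reads$contig_id))) {
    r <- reads[reads$contig_id == ctg, ]
    r <- r[order(r$read_id), ]
    lines <- c(lines,
               sprintf("##%s %d %d bases", ctg, nrow(r),
                       as.integer(contig_lengths[ctg])),
               sprintf("#%s(%d) [%s] %d bases", r$read_id,
                       as.integer(r$offset),
                       ifelse(r$orientation == "-", "RC", ""),
                       as.integer(r$length)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a Bambus-style mates file
#'
#' Inverse of [write_bambus_mates()]; mainly for round-trip validation.
#'
#' @param path Mates file path.
#' @return `list(libraries = <name/insert_min/insert_max>, pairs =
#'   <read_a/read_b/library>)`.
#' @export
read_bambus_mates <- function(path) {
  lines <- readLines(path)
  is_lib <- startsWith(lines, "library ")
  lib_f <- strsplit(lines[is_lib], " ", fixed = TRUE)
  libraries <- data.frame(
    name = vapply(lib_f, `[`, "", 2),
    insert_min = as.numeric(vapply(lib_f, `[`, "", 3)),
    insert_max = as.numeric(vapply(lib_f, `[`, "", 4)),
    stringsAsFactors = FALSE)
  pr_f <- strsplit(lines[!is_lib & nzchar(lines)], " ", fixed = TRUE)
  pairs <- data.frame(
    read_a = vapply(pr_f, `[`, "", 1),
    read_b = vapply(pr_f, `[`, "", 2),
    library = vapply(pr_f, `[`, "", 3),
    stringsAsFactors = FALSE)
  list(libraries = libraries, pairs = pairs)
}

#' Read back a Bambus-style contig file
#'
#' Inverse of [write_bambus_contig()]; mainly for round-trip validation.
#'
#' @param path Contig file path.
#' @return Data.frame with `read_id`, `contig_id`, `offset`, `length`,
#'   `orientation`.
#' @export
read_bambus_contig <- function(path) {
  lines <- readLines(path)
  out <- list(); ctg <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, "##")) {
      ctg <- sub("^##(\\S+) .*", "\\1", ln)
    } else if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec(
        "^#(.+)\\((-?[0-9]+)\\) \\[(RC)?\\] ([0-9]+) bases$", ln))[[1]]
      out[[length(out) + 1L]] <- data.frame(
        read_id = m[2], contig_id = ctg, offset = as.numeric(m[3]),
        length = as.numeric(m[5]),
        orientation = if (m[4] == "RC") "-" else "+",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(read_id = character(), contig_id = character(),
                      offset = numeric(), length = numeric(),
                      orientation = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
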