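#' Gene annotation BED I/O
#'
#' Gene annotations travel as 4-column BED (chrom, start, end, name) in the
#' usual 0-based half-open convention; in memory the package works in 1-based
#' inclusive coordinates, so the conversion happens here and only here.
#'
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, 1-based inclusive).
#' @param path file path.
#' @return `read_gene_bed` returns the in-memory annotation data.frame.
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(chrom = genes$chrom,
                   start = format(genes$start - 1, scientific = FALSE, trim = TRUE),
                   end = format(genes$end, scientific = FALSE, trim = TRUE),
                   name = genes$gene_id)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name"))
  out <- data.frame(gene_id = df$name, chrom = df$chrom,
                    start = df$start + 1, end = df$end,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end))
    stop("malformed BED: start >= end required in half-open coordinates",
         call. = FALSE)
  out
}

#' Subject table I/O
#'
#' Tab-separated subject table: `subject_id`, `phenotype` (0 = control,
#' 1 = case), `chip`, `study`.
#'
#' @param subjects subject data.frame.
#' @param path file path.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.table(subjects[, c("subject_id", "phenotype", "chip", "study")],
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          sep = "\t")
  stopifnot(all(c("subject_id", "phenotype", "chip", "study") %in% names(df)))
  if (!all(df$phenotype %in% c(0L, 1L)))
    stop("phenotype must be 0/1", call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Homology and probe table I/O
#'
#' Homology TSV columns: `group_id`, `source_gene_id`, `human_gene_id`.
#' Probe TSV columns: `probe_id`, `source_gene_id` (NA for probes with no
#' unique gene target), `p_mas5`, `p_rma`.
#'
#' @param x table to write.
#' @param path file path.
#' @export
write_homology_table <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_homology_table
#' @export
read_homology_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          sep = "\t")
  stopifnot(all(c("group_id", "source_gene_id", "human_gene_id") %in% names(df)))
  df
}

#' @rdname write_homology_table
#' @export
write_probe_table <- function(x, path) {
  utils::write.table(x, path, quote = FALSE, row.names = FALSE, sep = "\t",
                     na = "NA")
  invisible(path)
}

#' @rdname write_homology_table
#' @export
read_probe_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          sep = "\t", na.strings = "NA",
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  stopifnot(all(c("probe_id", "source_gene_id", "p_mas5", "p_rma") %in%
                  names(df)))
  df
}

#' Gene-set file I/O
#'
#' One gene per line, preceded by a `#` header carrying the set label and
#' selection fraction.
#'
#' @param gene_set a `gene_set` object from [select_top_fraction()].
#' @param path file path.
#' @export
write_gene_set <- function(gene_set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s fraction=%g", gene_set$label,
                     gene_set$fraction), con)
  writeLines(gene_set$members, con)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  label <- sub("^# label=(\\S+).*", "\\1", hdr)
  fraction <- as.numeric(sub(".*fraction=([0-9.eE+-]+).*", "\\1", hdr))
  members <- lines[-1]
  members <- members[nzchar(members)]
  structure(list(label = label, fraction = fraction, members = members),
            class = "gene_set")
}
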