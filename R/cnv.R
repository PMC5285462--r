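#' Read a PLINK-style .cnv file
#'
#' Parses the whitespace-delimited CNV dialect with columns
#' `FID IID CHR BP1 BP2 TYPE SCORE SITES` (header line optional). `TYPE`
#' codes follow copy-number convention: 1 = deletion, 3 = duplication.
#' Coordinates are 1-based inclusive; length is `BP2 - BP1 + 1`.
#'
#' @param path path to the .cnv file.
#' @param strict if TRUE (default), any malformed record (unknown TYPE code,
#'   `BP2 < BP1`, non-positive probe count) aborts with a message naming the
#'   offending line; if FALSE, such records are skipped with a warning.
#' @return A data.frame of CNV records: `subject_id`, `chrom`, `start`,
#'   `end`, `type` ("deletion"/"duplication"), `n_probes`, `length`.
#' @export
read_cnv_file <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("\\bFID\\b", first)
  raw <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) != 8L)
    stop("expected 8 columns (FID IID CHR BP1 BP2 TYPE SCORE SITES), got ",
         ncol(raw), call. = FALSE)
  names(raw) <- c("FID", "IID", "CHR", "BP1", "BP2", "TYPE", "SCORE", "SITES")
  line0 <- if (has_header) 1L else 0L
  bad <- rep(FALSE, nrow(raw))
  reason <- character(nrow(raw))
  unknown_type <- !(raw$TYPE %in% c(1L, 3L))
  bad[unknown_type] <- TRUE
  reason[unknown_type] <- sprintf("unknown TYPE code %s", raw$TYPE[unknown_type])
  inverted <- !bad & raw$BP2 < raw$BP1
  bad[inverted] <- TRUE
  reason[inverted] <- "BP2 < BP1"
  noprobe <- !bad & (is.na(raw$SITES) | raw$SITES < 1)
  bad[noprobe] <- TRUE
  reason[noprobe] <- "probe count < 1"
  if (any(bad)) {
    lines <- which(bad) + line0
    msg <- paste(sprintf("line %d: %s", lines, reason[bad]), collapse = "; ")
    if (strict) stop("malformed CNV records: ", msg, call. = FALSE)
    warning("skipping malformed CNV records: ", msg, call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
  }
  out <- data.frame(
    subject_id = as.character(raw$IID),
    chrom = as.character(raw$CHR),
    start = as.numeric(raw$BP1),
    end = as.numeric(raw$BP2),
    type = ifelse(raw$TYPE == 1L, "deletion", "duplication"),
    n_probes = as.integer(raw$SITES),
    stringsAsFactors = FALSE
  )
  out$length <- out$end - out$start + 1
  rownames(out) <- NULL
  out
}

#' Write CNV records in the PLINK-style .cnv dialect
#'
#' @param cnvs CNV data.frame as returned by [read_cnv_file()] or
#'   [gen_cnv_cohort()].
#' @param path output path.
#' @export
write_cnv_file <- function(cnvs, path) {
  df <- data.frame(
    FID = cnvs$subject_id,
    IID = cnvs$subject_id,
    CHR = cnvs$chrom,
    BP1 = format(cnvs$start, scientific = FALSE, trim = TRUE),
    BP2 = format(cnvs$end, scientific = FALSE, trim = TRUE),
    TYPE = ifelse(cnvs$type == "deletion", 1L, 3L),
    SCORE = 0,
    SITES = cnvs$n_probes
  )
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Filter CNVs on the standard reliability thresholds
#'
#' Retains calls at least `min_length` bp long and supported by at least
#' `min_probes` probes; both thresholds are inclusive. Removal counts by
#' reason are attached as attribute `removed` and reported via message.
#'
#' @param cnvs CNV data.frame.
#' @param min_length minimum length in bp (default 100 kb).
#' @param min_probes minimum supporting probe count (default 15).
#' @param quiet suppress the removal-count message.
#' @return The retained subset.
#' @export
filter_cnvs <- function(cnvs, min_length = 1e5, min_probes = 15L,
                        quiet = FALSE) {
  short <- cnvs$length < min_length
  sparse <- cnvs$n_probes < min_probes
  keep <- !short & !sparse
  out <- cnvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  removed <- c(too_short = sum(short), too_few_probes = sum(sparse & !short))
  attr(out, "removed") <- removed
  if (!quiet && any(removed > 0))
    message(sprintf("filter_cnvs: removed %d short (< %g bp) and %d sparse (< %d probes) of %d records",
                    removed[["too_short"]], min_length,
                    removed[["too_few_probes"]], min_probes, nrow(cnvs)))
  out
}

#' Restrict CNVs to one variant class
#'
#' @param cnvs CNV data.frame.
#' @param which one of "all", "deletion", "duplication".
#' @return Filtered view; `which = "all"` is the identity.
#' @export
stratify_by_type <- function(cnvs, which = c("all", "deletion", "duplication")) {
  which <- match.arg(which)
  if (which == "all") return(cnvs)
  out <- cnvs[cnvs$type == which, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("no ", which, " CNVs in input", call. = FALSE)
  out
}

# GRanges views of the two interval tables. CNVs arrive 1-based inclusive;
# GRanges is itself 1-based inclusive so no shift is needed for them. Gene
# annotation here is 1-based inclusive too (BED I/O does the 0-based
# conversion at the file boundary).
.gene_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         gene_id = genes$gene_id)
}

.cnv_granges <- function(cnvs) {
  GenomicRanges::GRanges(cnvs$chrom, IRanges::IRanges(cnvs$start, cnvs$end))
}

#' Annotate CNVs with their overlapping genes
#'
#' A gene is hit when its interval shares at least one base with the CNV
#' (any-overlap rule); `min_overlap_frac` optionally requires that at least
#' that fraction of the gene's length be covered.
#'
#' @param cnvs CNV data.frame (1-based inclusive coordinates).
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, 1-based inclusive; use [read_gene_bed()] for BED input).
#' @param min_overlap_frac minimum fraction of the gene covered (default 0 =
#'   any overlap).
#' @return The CNV data.frame with an added list-column `genes_hit` (character
#'   vector of gene ids per CNV) and integer column `n_genes_hit`. CNVs on
#'   chromosomes absent from the annotation get empty hit sets (reported once
#'   per chromosome).
#' @export
annotate_cnvs <- function(cnvs, genes, min_overlap_frac = 0) {
  out <- cnvs
  if (nrow(cnvs) == 0) {
    out$genes_hit <- list()
    out$n_genes_hit <- integer(0)
    return(out)
  }
  missing_chr <- setdiff(unique(cnvs$chrom), unique(genes$chrom))
  if (length(missing_chr) > 0)
    message("annotate_cnvs: no annotation for chromosome(s) ",
            paste(missing_chr, collapse = ", "))
  gr_c <- .cnv_granges(cnvs)
  gr_g <- .gene_granges(genes)
  hits <- GenomicRanges::findOverlaps(gr_c, gr_g)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (min_overlap_frac > 0 && length(qh) > 0) {
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_c)[qh], IRanges::ranges(gr_g)[sh]))
    keep <- ov / IRanges::width(gr_g)[sh] >= min_overlap_frac
    qh <- qh[keep]; sh <- sh[keep]
  }
  hit_list <- split(genes$gene_id[sh], factor(qh, levels = seq_len(nrow(cnvs))))
  out$genes_hit <- unname(lapply(hit_list, as.character))
  out$n_genes_hit <- lengths(out$genes_hit)
  out
}

#' Long-format CNV-to-gene pairs from an annotated CNV table
#'
#' One row per (CNV, gene) overlap; convenient for audit output and for
#' building the subject-by-gene hit structure.
#'
#' @param annotated output of [annotate_cnvs()].
#' @return data.frame with the CNV columns plus one `gene_id` per row.
#' @export
cnv_gene_pairs <- function(annotated) {
  n <- lengths(annotated$genes_hit)
  base <- annotated[rep(seq_len(nrow(annotated)), n),
                    setdiff(names(annotated), c("genes_hit", "n_genes_hit")),
                    drop = FALSE]
  base$gene_id <- unlist(annotated$genes_hit, use.names = FALSE)
  rownames(base) <- NULL
  base
}
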