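## Input/output: methylation tables, BED regions, gene annotation,
## expression matrices, FASTA genomes, feature tables.
## All internal coordinates are 0-based half-open (BED convention).

#' Construct a methylome from a data frame of per-CpG counts
#'
#' A methylome holds the coverage-filtered CpG methylation profile of one
#' cell line. Each site records the number of methylated reads and the
#' total read count at the C of a CpG dinucleotide (forward strand,
#' 0-based position); the methylation level is their ratio.
#'
#' @param x data frame with columns `chrom`, `pos`, `meth_count`,
#'   `total_count` (extra columns are dropped).
#' @param cell_line identifier for the cell line.
#' @param min_coverage minimum total read count for a site to be kept
#'   (default 5, i.e. sites covered by more than 4 reads).
#' @param merge_strands if `TRUE`, a record at position `pos + 1`
#'   immediately following a record at `pos` is treated as the
#'   G-strand read-out of the same CpG and its counts are summed into the
#'   forward-strand site. CpG methylation is symmetric, so strand-split
#'   input files carry one biological site as two adjacent records.
#' @return an object of class `methylome` (a sorted `data.table` with a
#'   computed `level` column and attributes `cell_line`, `min_coverage`,
#'   `n_dropped`).
#' @export
methylome <- function(x, cell_line = "cell", min_coverage = 5,
                      merge_strands = FALSE) {
  stopifnot(min_coverage >= 1)
  dt <- data.table::as.data.table(x)
  req <- c("chrom", "pos", "meth_count", "total_count")
  if (!all(req %in% names(dt))) {
    stop("methylome input needs columns: ", paste(req, collapse = ", "))
  }
  dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
               meth_count = as.integer(meth_count),
               total_count = as.integer(total_count))]
  bad <- which(is.na(dt$pos) | is.na(dt$meth_count) | is.na(dt$total_count))
  if (length(bad)) stop("non-numeric or missing value at record ", bad[1L])
  if (any(dt$meth_count < 0L)) {
    stop("negative meth_count at record ", which(dt$meth_count < 0L)[1L])
  }
  if (any(dt$total_count < 1L)) {
    stop("non-positive total_count at record ", which(dt$total_count < 1L)[1L])
  }
  bad <- which(dt$meth_count > dt$total_count)
  if (length(bad)) {
    stop("meth_count exceeds total_count at record ", bad[1L])
  }
  data.table::setorder(dt, chrom, pos)
  if (merge_strands && nrow(dt) > 1L) {
    prev_pos <- data.table::shift(dt$pos)
    prev_chr <- data.table::shift(dt$chrom)
    second <- !is.na(prev_pos) & dt$chrom == prev_chr & dt$pos == prev_pos + 1L
    dt[, anchor := pos]
    dt$anchor[second] <- dt$pos[second] - 1L
    dt <- dt[, .(meth_count = sum(meth_count),
                 total_count = sum(total_count)), by = .(chrom, pos = anchor)]
  }
  n0 <- nrow(dt)
  dt <- dt[total_count >= min_coverage]
  n_dropped <- n0 - nrow(dt)
  if (n_dropped > 0L) {
    message("methylome [", cell_line, "]: dropped ", n_dropped,
            " site(s) below coverage ", min_coverage)
  }
  if (anyDuplicated(dt, by = c("chrom", "pos"))) {
    stop("duplicate CpG positions in methylome (use merge_strands for ",
         "strand-split input)")
  }
  dt[, level := meth_count / total_count]
  data.table::setattr(dt, "class",
                      c("methylome", "data.table", "data.frame"))
  data.table::setattr(dt, "cell_line", cell_line)
  data.table::setattr(dt, "min_coverage", min_coverage)
  data.table::setattr(dt, "n_dropped", n_dropped)
  dt[]
}

#' Read a per-CpG methylation table
#'
#' Reads a tab-separated methylation table into a [methylome]. The
#' default dialect has four columns `chrom pos meth_count total_count`
#' with no header; the `bismark` dialect accepts the six-column bismark
#' coverage format (`chrom start end pct count_meth count_unmeth`,
#' 1-based).
#'
#' @param path file path.
#' @param cell_line cell-line identifier; defaults to the file stem.
#' @param min_coverage minimum total read count to keep a site (default 5).
#' @param dialect `"simple"` (default) or `"bismark"`.
#' @param one_based set `TRUE` if the `pos` column of the simple dialect
#'   is 1-based; positions are shifted to the internal 0-based convention.
#'   Ignored for the bismark dialect, which is always 1-based.
#' @param merge_strands see [methylome()].
#' @return a `methylome`.
#' @export
read_methylome <- function(path, cell_line = NULL, min_coverage = 5,
                           dialect = c("simple", "bismark"),
                           one_based = FALSE, merge_strands = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("methylome file not found: ", path)
  if (is.null(cell_line)) cell_line <- sub("\\.[^.]*$", "", basename(path))
  empty <- data.frame(chrom = character(), pos = integer(),
                      meth_count = integer(), total_count = integer())
  if (file.size(path) == 0L) {
    warning("empty methylome file: ", path)
    return(methylome(empty, cell_line = cell_line,
                     min_coverage = min_coverage))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (dialect == "simple") {
    if (ncol(dt) < 4L) stop("expected >= 4 columns in ", path)
    dt <- dt[, 1:4]
    data.table::setnames(dt, c("chrom", "pos", "meth_count", "total_count"))
    for (cn in c("pos", "meth_count", "total_count")) {
      v <- suppressWarnings(as.numeric(dt[[cn]]))
      if (anyNA(v)) {
        stop("parse error in ", path, " at line ", which(is.na(v))[1L],
             ": non-numeric '", cn, "'")
      }
      data.table::set(dt, j = cn, value = v)
    }
    if (one_based) dt[, pos := pos - 1L]
  } else {
    if (ncol(dt) < 6L) stop("expected 6 bismark coverage columns in ", path)
    dt <- dt[, .(chrom = as.character(dt[[1L]]),
                 pos = as.integer(dt[[2L]]) - 1L,
                 meth_count = as.integer(dt[[5L]]),
                 total_count = as.integer(dt[[5L]]) + as.integer(dt[[6L]]))]
    if (anyNA(dt$pos)) {
      stop("parse error in ", path, " at line ", which(is.na(dt$pos))[1L])
    }
  }
  methylome(dt, cell_line = cell_line, min_coverage = min_coverage,
            merge_strands = merge_strands)
}

#' Write a methylome to the simple four-column dialect
#' @param m a `methylome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(m, path) {
  stopifnot(inherits(m, "methylome"))
  data.table::fwrite(m[, .(chrom, pos, meth_count, total_count)], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

.region_labels <- c("positive", "background")
.region_classes <- c("promoter", "enhancer")

#' Construct a set of labeled genomic regions
#'
#' @param chrom,start,end region coordinates, 0-based half-open.
#' @param label `"positive"` (regulatory) or `"background"` (sampled
#'   random region), recycled.
#' @param region_class `"promoter"` or `"enhancer"`, recycled.
#' @param region_id unique identifiers; autogenerated when `NULL`.
#' @param source_id for background regions, the id of the positive region
#'   they were matched to.
#' @param replicate background replicate index within a source region.
#' @param target_gene optional assigned target gene id.
#' @return an object of class `region_set` (a `data.table`).
#' @export
region_set <- function(chrom, start, end, label = "positive",
                       region_class = "promoter", region_id = NULL,
                       source_id = NA_character_, replicate = NA_integer_,
                       target_gene = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (any(is.na(start) | is.na(end))) stop("missing region coordinates")
  bad <- which(start >= end)
  if (length(bad)) {
    stop("invalid interval (start >= end) at record ", bad[1L])
  }
  if (any(start < 0L)) stop("negative start coordinate")
  if (!all(label %in% .region_labels)) {
    stop("label must be one of: ", paste(.region_labels, collapse = ", "))
  }
  if (!all(region_class %in% .region_classes)) {
    stop("region_class must be one of: ",
         paste(.region_classes, collapse = ", "))
  }
  if (is.null(region_id)) {
    region_id <- sprintf("%s:%d-%d", chrom, start, end)
    if (anyDuplicated(region_id)) {
      region_id <- paste0(region_id, "_", seq_len(n))
    }
  }
  if (anyDuplicated(region_id)) stop("duplicate region_id values")
  dt <- data.table::data.table(
    region_id = as.character(region_id), chrom = as.character(chrom),
    start = start, end = end,
    label = rep_len(label, n), region_class = rep_len(region_class, n),
    source_id = rep_len(as.character(source_id), n),
    replicate = rep_len(as.integer(replicate), n),
    target_gene = rep_len(as.character(target_gene), n))
  data.table::setattr(dt, "class",
                      c("region_set", "data.table", "data.frame"))
  dt[]
}

#' Read candidate regions from a BED file
#'
#' BED3+ input, 0-based half-open. A 4th column, when present, is used as
#' the region id. Overlapping records are kept as-is (no merging); the
#' number of overlapping pairs is reported.
#'
#' @param path BED file path.
#' @param label,region_class labels applied uniformly to all records.
#' @param genome optional named `DNAStringSet`; when supplied, records on
#'   chromosomes absent from the genome raise an error.
#' @return a `region_set`, sorted by coordinate.
#' @export
read_regions <- function(path, label = "positive",
                         region_class = "promoter", genome = NULL) {
  if (!file.exists(path)) stop("region file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 3L) stop("expected BED3+ in ", path)
  st <- suppressWarnings(as.integer(dt[[2L]]))
  en <- suppressWarnings(as.integer(dt[[3L]]))
  if (anyNA(st) || anyNA(en)) {
    stop("parse error in ", path, " at line ",
         which(is.na(st) | is.na(en))[1L])
  }
  bad <- which(st >= en)
  if (length(bad)) {
    stop("invalid interval (start >= end) in ", path, " at line ", bad[1L])
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(dt[[1L]]), names(genome))
    if (length(unknown)) {
      stop("chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "))
    }
  }
  ids <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NULL
  rs <- region_set(dt[[1L]], st, en, label = label,
                   region_class = region_class, region_id = ids)
  gr <- .as_granges(rs)
  n_ov <- sum(GenomicRanges::countOverlaps(gr, gr) > 1L)
  if (n_ov > 0L) message(n_ov, " record(s) in ", basename(path),
                         " overlap another record (kept as-is)")
  data.table::setorder(rs, chrom, start, end)
  rs[]
}

#' Write a region set as BED
#'
#' Background regions are named `<source_id>:<replicate>`, other regions
#' by their `region_id`.
#' @param rs a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(rs, path) {
  stopifnot(inherits(rs, "region_set"))
  nm <- ifelse(!is.na(rs$source_id),
               paste0(rs$source_id, ":", rs$replicate), rs$region_id)
  data.table::fwrite(data.table::data.table(rs$chrom, rs$start, rs$end, nm),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Construct a gene annotation table
#'
#' @param x data frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end` (0-based half-open) and list columns (or
#'   comma-separated strings) `exon_starts`, `exon_ends`.
#' @return an object of class `gene_annotation`: a `data.table` with
#'   derived columns `tss` (the transcription start coordinate:
#'   `tx_start` on `+`, `tx_end` on `-`) and `coding_length`
#'   (`tx_end - tx_start`), plus validated exon list columns ordered by
#'   genomic coordinate.
#' @export
gene_annotation <- function(x) {
  dt <- data.table::as.data.table(x)
  req <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
           "exon_starts", "exon_ends")
  if (!all(req %in% names(dt))) {
    stop("gene annotation needs columns: ", paste(req, collapse = ", "))
  }
  parse_list <- function(v) {
    if (is.list(v)) lapply(v, as.integer)
    else lapply(strsplit(as.character(v), ","), as.integer)
  }
  dt[, `:=`(gene_id = as.character(gene_id), chrom = as.character(chrom),
            strand = as.character(strand), tx_start = as.integer(tx_start),
            tx_end = as.integer(tx_end))]
  dt[, exon_starts := parse_list(exon_starts)]
  dt[, exon_ends := parse_list(exon_ends)]
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(dt$tx_start >= dt$tx_end)) stop("tx_start must be < tx_end")
  if (anyDuplicated(dt$gene_id)) stop("duplicate gene_id values")
  for (i in seq_len(nrow(dt))) {
    es <- dt$exon_starts[[i]]; ee <- dt$exon_ends[[i]]
    if (length(es) != length(ee)) {
      stop("gene ", dt$gene_id[i], ": exon start/end lists differ in length")
    }
    if (length(es) == 0L) stop("gene ", dt$gene_id[i], ": no exons")
    if (any(es >= ee)) stop("gene ", dt$gene_id[i], ": invalid exon interval")
    o <- order(es)
    es <- es[o]; ee <- ee[o]
    if (any(es[-1L] < ee[-length(ee)])) {
      stop("gene ", dt$gene_id[i], ": overlapping exons")
    }
    if (es[1L] < dt$tx_start[i] || ee[length(ee)] > dt$tx_end[i]) {
      stop("gene ", dt$gene_id[i], ": exons outside gene span")
    }
    dt$exon_starts[[i]] <- es; dt$exon_ends[[i]] <- ee
  }
  dt[, tss := ifelse(strand == "+", tx_start, tx_end)]
  dt[, coding_length := tx_end - tx_start]
  data.table::setattr(dt, "class",
                      c("gene_annotation", "data.table", "data.frame"))
  dt[]
}

#' Read a UCSC-style gene annotation table
#'
#' Expects a header row and columns `gene_id`, `chrom`, `strand`,
#' `tx_start`, `tx_end`, `exon_starts`, `exon_ends` with comma-separated
#' exon coordinates (0-based half-open).
#' @param path file path.
#' @return a `gene_annotation`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("gene annotation file not found: ", path)
  gene_annotation(data.table::fread(path, header = TRUE, sep = "\t"))
}

#' Write a gene annotation table
#' @param genes a `gene_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  stopifnot(inherits(genes, "gene_annotation"))
  out <- data.table::data.table(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tx_start = genes$tx_start, tx_end = genes$tx_end,
    exon_starts = vapply(genes$exon_starts, paste, "", collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, "", collapse = ","))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an expression matrix (genes x cell lines, RPKM)
#'
#' First column holds gene ids, remaining columns one cell line each.
#' Missing values stay `NA` (absent, not zero); negative values are
#' rejected.
#' @param path file path.
#' @return a numeric matrix with gene-id rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (ncol(dt) < 2L) stop("expected gene id plus >= 1 cell line in ", path)
  m <- as.matrix(dt[, -1L])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(dt[[1L]])
  if (any(m < 0, na.rm = TRUE)) {
    stop("negative RPKM value in ", path)
  }
  m
}

#' Write an expression matrix
#' @param expr numeric matrix, gene ids as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  out <- data.table::data.table(gene_id = rownames(expr))
  for (cn in colnames(expr)) out[[cn]] <- expr[, cn]
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return a named `DNAStringSet` (names truncated at first whitespace).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a feature table
#'
#' Tab-separated with header; floating point values are written with 17
#' significant digits so that a write/read round trip is lossless.
#' @param ft a feature table ([build_feature_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  if (is.null(ft) || nrow(ft) == 0L) stop("empty feature table: ", path)
  out <- data.table::copy(data.table::as.data.table(ft))
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      data.table::set(out, j = cn, value = sprintf("%.17g", out[[cn]]))
    }
  }
  tryCatch(data.table::fwrite(out, path, sep = "\t"),
           error = function(e) stop("cannot write feature table to ", path,
                                    ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path file path.
#' @return a `feature_table` `data.table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  data.table::setattr(dt, "class",
                      c("feature_table", "data.table", "data.frame"))
  dt[]
}

## GRanges helpers -----------------------------------------------------------

# region_set/methylome -> GRanges on a shared seqlevel universe
.as_granges <- function(rs, levels = NULL) {
  if (is.null(levels)) levels <- unique(rs$chrom)
  GenomicRanges::GRanges(
    factor(rs$chrom, levels = levels),
    IRanges::IRanges(rs$start + 1L, rs$end))
}

.sites_granges <- function(m, levels = NULL) {
  if (is.null(levels)) levels <- unique(m$chrom)
  GenomicRanges::GRanges(
    factor(m$chrom, levels = levels),
    IRanges::IRanges(m$pos + 1L, width = 1L))
}

# all mCpG sites falling in each region: data.table(region_id, chrom, pos, level)
.sites_in_regions <- function(regions, m) {
  lv <- union(unique(regions$chrom), unique(m$chrom))
  if (nrow(regions) == 0L || nrow(m) == 0L) {
    return(data.table::data.table(region_id = character(),
                                  chrom = character(), pos = integer(),
                                  level = numeric()))
  }
  ov <- GenomicRanges::findOverlaps(.as_granges(regions, lv),
                                    .sites_granges(m, lv))
  st <- data.table::data.table(
    region_id = regions$region_id[S4Vectors::queryHits(ov)],
    chrom = m$chrom[S4Vectors::subjectHits(ov)],
    pos = m$pos[S4Vectors::subjectHits(ov)],
    level = m$level[S4Vectors::subjectHits(ov)])
  data.table::setorder(st, region_id, pos)
  st[]
}
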