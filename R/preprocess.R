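#' Construct a methylation matrix container
#'
#' A light container for a probe-by-sample methylation matrix with per-probe
#' genomic metadata.  Values are either on the beta scale (bounded in
#' `[0, 1]`) or the M-value scale (logit2 of beta, unbounded); the scale is
#' flagged so downstream code can insist on M-values for linear modelling.
#'
#' @param values numeric probe x sample matrix.
#' @param chrom,pos chromosome label and 1-based coordinate per probe
#'   (`NA` allowed; probes without coordinates are dropped by
#'   [filter_probes()]).
#' @param probe_ids unique probe identifiers; defaults to the matrix
#'   rownames.
#' @param sample_ids ordered sample identifiers; defaults to the matrix
#'   colnames.
#' @param scale `"beta"` or `"M"`.
#'
#' @return a list of class `"methylation_matrix"`.
#' @export
methylation_matrix <- function(values, chrom, pos,
                               probe_ids = rownames(values),
                               sample_ids = colnames(values),
                               scale = c("beta", "M")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(probe_ids)) stop("probe ids are required")
  if (anyDuplicated(probe_ids)) stop("probe ids must be unique")
  if (length(probe_ids) != nrow(values))
    stop("probe ids do not match the matrix rows")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(ncol(values)))
  if (length(chrom) != nrow(values) || length(pos) != nrow(values))
    stop("chrom/pos must have one entry per probe")
  if (scale == "beta") {
    finite <- values[is.finite(values)]
    if (length(finite) && (min(finite) < 0 || max(finite) > 1))
      stop("beta-scale values must lie in [0, 1]")
  }
  rownames(values) <- probe_ids
  colnames(values) <- sample_ids
  structure(list(probe_ids = as.character(probe_ids),
                 chrom = as.character(chrom), pos = as.integer(pos),
                 values = values, sample_ids = as.character(sample_ids),
                 scale = scale),
            class = "methylation_matrix")
}

#' @export
dim.methylation_matrix <- function(x) dim(x$values)

#' Logit2 transform between beta values and M-values
#'
#' `beta_to_mvalue()` maps a beta value in `[0, 1]` to the unbounded
#' M-value `log2(b / (1 - b))` after clipping `b` into
#' `[epsilon, 1 - epsilon]` to keep the transform finite at the boundaries;
#' base-2 logarithm is the array-methylation convention.
#' `mvalue_to_beta()` is the inverse on the open clipped interval.
#'
#' @param beta beta value(s) in `[0, 1]`; values outside are rejected with a
#'   diagnostic naming how many offend.
#' @param m M-value(s).
#' @param epsilon clip bound in `(0, 0.5)`.
#' @return numeric vector of the same length.
#' @examples
#' beta_to_mvalue(0.5)  # 0
#' beta_to_mvalue(0.8)  # 2
#' @export
beta_to_mvalue <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    stop("'epsilon' must lie in (0, 0.5)")
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad))
    stop(sprintf("%d beta value(s) outside [0, 1]; reject those probes",
                 sum(bad)))
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' @rdname beta_to_mvalue
#' @export
mvalue_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' Filter probes by identifier class, sex chromosome and blacklist
#'
#' Removes, in order: non-CpG control probes whose identifier starts with
#' `"ch."`; probes on sex chromosomes (spellings `"X"`, `"chrX"`, `"Y"`,
#' `"chrY"`); probes on a user-supplied blacklist (e.g. a published
#' cross-reactive-probe list); probes with missing chromosome or position.
#' Each probe is counted once, under the first rule that removes it.
#'
#' @param matrix a [methylation_matrix()].
#' @param blacklist character vector of probe ids (may be empty).
#' @return list with the filtered `matrix` and a `report` of per-rule
#'   removal counts.
#' @export
filter_probes <- function(matrix, blacklist = character()) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  ids <- matrix$probe_ids
  is_ch <- startsWith(ids, "ch.")
  is_sex <- !is_ch & matrix$chrom %in% c("X", "chrX", "Y", "chrY")
  is_black <- !is_ch & !is_sex & ids %in% blacklist
  is_nopos <- !is_ch & !is_sex & !is_black &
    (is.na(matrix$chrom) | is.na(matrix$pos))
  keep <- !(is_ch | is_sex | is_black | is_nopos)
  report <- c(ch = sum(is_ch), sex = sum(is_sex),
              blacklist = sum(is_black), missing_coord = sum(is_nopos),
              kept = sum(keep))
  if (!any(keep))
    warning("all probes removed by filtering")
  filtered <- methylation_matrix(matrix$values[keep, , drop = FALSE],
                                 chrom = matrix$chrom[keep],
                                 pos = matrix$pos[keep],
                                 probe_ids = ids[keep],
                                 sample_ids = matrix$sample_ids,
                                 scale = matrix$scale)
  list(matrix = filtered, report = report)
}

#' Map CpG probes to promoter-extended gene regions
#'
#' Extends each gene's body upstream of the transcription start site by
#' `upstream` bp in a strand-aware way (`+` strand: `[start - upstream,
#' end]`; `-` strand: `[start, end + upstream]`) so promoters are included,
#' then assigns every probe on the same chromosome whose position falls
#' inside the extended interval.  A probe may belong to several overlapping
#' genes.  Genes with zero member probes are excluded and reported.
#'
#' @param annotation data.frame with columns `gene`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive).
#' @param matrix a [methylation_matrix()].
#' @param upstream bp count of the promoter extension (default 500).
#' @return a data.frame gene map with the extended bounds, member probe-id
#'   list column `probes` and per-gene CpG count `K`; dropped empty genes
#'   are recorded in the `"dropped"` attribute.
#' @export
map_cpgs_to_genes <- function(annotation, matrix, upstream = 500L) {
  stopifnot(inherits(matrix, "methylation_matrix"))
  need <- c("gene", "chrom", "strand", "start", "end")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (!all(annotation$strand %in% c("+", "-")))
    stop("malformed strand: only '+' and '-' are supported")
  if (any(annotation$start > annotation$end))
    stop("gene with start > end in annotation")
  if (upstream < 0) stop("'upstream' must be >= 0")

  ext_start <- ifelse(annotation$strand == "+",
                      pmax(1L, annotation$start - as.integer(upstream)),
                      annotation$start)
  ext_end <- ifelse(annotation$strand == "+",
                    annotation$end,
                    annotation$end + as.integer(upstream))

  ok <- !is.na(matrix$chrom) & !is.na(matrix$pos)
  probes <- GenomicRanges::GRanges(
    seqnames = matrix$chrom[ok],
    ranges = IRanges::IRanges(start = matrix$pos[ok], width = 1L))
  genes <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = ext_start, end = ext_end))
  hits <- GenomicRanges::findOverlaps(probes, genes, ignore.strand = TRUE)
  probe_ids_ok <- matrix$probe_ids[ok]
  members <- split(probe_ids_ok[S4Vectors::queryHits(hits)],
                   factor(S4Vectors::subjectHits(hits),
                          levels = seq_len(nrow(annotation))))

  out <- data.frame(gene = annotation$gene, chrom = annotation$chrom,
                    strand = annotation$strand,
                    start = annotation$start, end = annotation$end,
                    extended_start = ext_start, extended_end = ext_end,
                    K = unname(lengths(members)), stringsAsFactors = FALSE)
  out$probes <- unname(members)
  empty <- out$K == 0L
  if (any(empty))
    message(sum(empty), " gene(s) with zero member probes excluded from testing")
  dropped <- out$gene[empty]
  out <- out[!empty, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Read a methylation matrix from TSV
#'
#' The first column is the probe id; optional `chrom`/`chr` and
#' `pos`/`position` columns carry probe coordinates; all remaining columns
#' are samples.  Gzipped files are accepted.  With `scale = "auto"` the
#' matrix is flagged as beta-scale when every finite value lies in
#' `[0, 1]`, otherwise as M-values.
#'
#' @param path TSV file path.
#' @param scale `"auto"`, `"beta"` or `"M"`.
#' @return a [methylation_matrix()].
#' @export
read_methylation <- function(path, scale = c("auto", "beta", "M")) {
  scale <- match.arg(scale)
  dt <- data.table::fread(path, sep = "\t", data.table = TRUE)
  ids <- as.character(dt[[1L]])
  nm <- names(dt)
  chrom_col <- intersect(c("chrom", "chr", "chromosome"), nm)[1]
  pos_col <- intersect(c("pos", "position"), nm)[1]
  chrom <- if (!is.na(chrom_col)) as.character(dt[[chrom_col]]) else
    rep(NA_character_, nrow(dt))
  pos <- if (!is.na(pos_col)) as.integer(dt[[pos_col]]) else
    rep(NA_integer_, nrow(dt))
  drop_cols <- c(nm[1L], chrom_col, pos_col)
  drop_cols <- drop_cols[!is.na(drop_cols)]
  vals <- as.matrix(dt[, setdiff(nm, drop_cols), with = FALSE])
  if (scale == "auto") {
    finite <- vals[is.finite(vals)]
    scale <- if (length(finite) && min(finite) >= 0 && max(finite) <= 1)
      "beta" else "M"
  }
  methylation_matrix(vals, chrom = chrom, pos = pos, probe_ids = ids,
                     sample_ids = setdiff(nm, drop_cols), scale = scale)
}

#' Read a per-sample phenotype table from CSV
#'
#' @param path CSV file path (gzip accepted).
#' @return a data.frame, one row per sample.
#' @export
read_phenotypes <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Read a gene annotation from BED or GFF3
#'
#' BED input (0-based half-open) is converted to the package's 1-based
#' inclusive convention on read, with a message recording the conversion;
#' GFF3 input is already 1-based and its `type == "gene"` records are used
#' when present.  Gzipped files are accepted.
#'
#' @param path file path ending in `.bed`, `.gff`, `.gff3` (optionally
#'   `.gz`).
#' @return a data.frame with columns `gene`, `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive).
#' @export
read_annotation <- function(path) {
  base <- sub("\\.gz$", "", path)
  is_bed <- grepl("\\.bed$", base, ignore.case = TRUE)
  gr <- rtracklayer::import(path)
  if (is_bed)
    message("BED input: converted 0-based half-open to 1-based inclusive")
  meta <- S4Vectors::mcols(gr)
  if (!is_bed && "type" %in% names(meta) && any(meta$type == "gene"))
    gr <- gr[meta$type == "gene"]
  meta <- S4Vectors::mcols(gr)
  gene <- if ("name" %in% names(meta) && !all(is.na(meta$name))) {
    as.character(meta$name)
  } else if ("Name" %in% names(meta) && !all(is.na(meta$Name))) {
    as.character(meta$Name)
  } else if ("ID" %in% names(meta)) {
    as.character(meta$ID)
  } else {
    sprintf("gene%05d", seq_along(gr))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("malformed strand: annotation records without strand")
  data.frame(gene = gene,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a probe blacklist, one probe id per line
#'
#' @param path file path (gzip accepted); `NULL` or `""` gives an empty
#'   blacklist.
#' @return character vector of probe ids.
#' @export
read_blacklist <- function(path) {
  if (is.null(path) || !nzchar(path)) return(character())
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  ids <- readLines(con)
  ids[nzchar(trimws(ids))]
}
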