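# File-format readers and writers.  All readers reject malformed input with
# the offending location rather than silently coercing.  Coordinates are
# 1-based inclusive (VCF convention); windows are inclusive at both ends.

#' Read an expression TSV (first column gene ids, header of sample ids)
#'
#' @param path TSV path.
#' @return genes x samples numeric matrix.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression table needs gene ids plus samples")
  genes <- tab[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(num)[bad[1, 2]]))
  nas <- which(is.na(num), arr.ind = TRUE)
  if (nrow(nas))
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 genes[nas[1, 1]], colnames(num)[nas[1, 2]]))
  num
}

#' Write an expression matrix as TSV
#'
#' Full double precision, so write-then-read round-trips exactly.
#'
#' @param expr genes x samples matrix.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(is.matrix(expr))
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample annotations as TSV
#' @param annotations data.frame (`sample_id`, `timepoint`, `cell`).
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from a dosage TSV or a minimal VCF
#'
#' Dosage TSV: columns `snp`, `chr`, `pos`, then one column per individual
#' with dosages in {0,1,2}.  Minimal VCF: GT genotypes only; multi-allelic
#' sites are rejected; malformed lines are rejected with their line number.
#' MAF is computed from the dosages when not supplied.
#'
#' @param path input path (`.vcf` detected by extension or `##fileformat`).
#' @return A list with `dosage` (SNPs x individuals integer matrix) and
#'   `snp_info` (data.frame `snp`, `chr`, `pos`, `maf`).
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.vcf$", path, ignore.case = TRUE) ||
      startsWith(first, "##fileformat"))
    read_minimal_vcf(path)
  else
    read_dosage_tsv(path)
}

read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stop_if_not_named_df(tab, c("snp", "chr", "pos"), "dosage table")
  ind <- setdiff(names(tab), c("snp", "chr", "pos", "maf"))
  if (!length(ind)) stop("dosage table has no individual columns")
  d <- as.matrix(tab[, ind, drop = FALSE])
  if (!is.numeric(d) || any(is.na(d)) || any(!d %in% 0:2))
    stop("dosages must be 0, 1 or 2 with no missing values")
  storage.mode(d) <- "integer"
  rownames(d) <- tab$snp
  maf <- tab$maf %||% pmin(rowMeans(d) / 2, 1 - rowMeans(d) / 2)
  list(dosage = d,
       snp_info = data.frame(snp = tab$snp, chr = as.character(tab$chr),
                             pos = tab$pos, maf = maf,
                             stringsAsFactors = FALSE))
}

read_minimal_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (!length(hdr_i)) stop("VCF has no #CHROM header line")
  hdr <- strsplit(lines[hdr_i[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("VCF has no sample columns")
  samples <- hdr[-(1:9)]
  body_i <- setdiff(seq_along(lines), c(grep("^#", lines)))
  rows <- lapply(body_i, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdr))
      stop(sprintf("malformed VCF line %d: %d fields, expected %d",
                   i, length(f), length(hdr)))
    if (grepl(",", f[5], fixed = TRUE))
      stop(sprintf("multi-allelic site at line %d (%s)", i, f[3]))
    gt <- sub(":.*", "", f[-(1:9)])
    dos <- vapply(gt, function(g) {
      a <- strsplit(g, "[/|]")[[1]]
      if (length(a) != 2 || !all(a %in% c("0", "1")))
        return(NA_integer_)
      sum(a == "1")
    }, integer(1), USE.NAMES = FALSE)
    if (anyNA(dos))
      stop(sprintf("malformed GT on VCF line %d", i))
    list(snp = f[3], chr = f[1], pos = as.numeric(f[2]), dos = dos)
  })
  d <- do.call(rbind, lapply(rows, `[[`, "dos"))
  rownames(d) <- vapply(rows, `[[`, character(1), "snp")
  colnames(d) <- samples
  storage.mode(d) <- "integer"
  frq <- rowMeans(d) / 2
  list(dosage = d,
       snp_info = data.frame(snp = rownames(d),
                             chr = vapply(rows, `[[`, character(1), "chr"),
                             pos = vapply(rows, `[[`, numeric(1), "pos"),
                             maf = pmin(frq, 1 - frq),
                             stringsAsFactors = FALSE))
}

#' Write genotype dosages as a dosage TSV or a minimal VCF (GT only)
#'
#' @param dosage SNPs x individuals matrix with values in {0,1,2}.
#' @param snp_info data.frame `snp`, `chr`, `pos` (order defines row order).
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path` invisibly.
#' @export
write_genotypes <- function(dosage, snp_info, path,
                            format = c("tsv", "vcf")) {
  format <- match.arg(format)
  snp_info <- snp_info[match(rownames(dosage), snp_info$snp), ]
  if (format == "tsv") {
    df <- data.frame(snp = snp_info$snp, chr = snp_info$chr,
                     pos = snp_info$pos, dosage, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], nrow = nrow(dosage))
    lines <- c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(dosage)), collapse = "\t"),
               vapply(seq_len(nrow(dosage)), function(i)
                 paste(c(snp_info$chr[i], format(snp_info$pos[i],
                                                 scientific = FALSE),
                         snp_info$snp[i], "A", "G", ".", "PASS", ".", "GT",
                         gt[i, ]), collapse = "\t"), character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write a GWAS summary TSV (snp, chr, pos, p, maf)
#'
#' @param path TSV path.
#' @return data.frame with the five columns.
#' @export
read_gwas <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_named_df(tab, c("snp", "chr", "pos", "p"), "GWAS summary")
  if (any(!is.finite(tab$p)) || any(tab$p <= 0 | tab$p > 1))
    stop("GWAS P-values must lie in (0, 1]")
  tab
}

#' @rdname read_gwas
#' @param gwas data.frame to write.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(format(gwas, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a TF network as SIF and companion TSV
#'
#' SIF lines read `tf<TAB>regulates<TAB>partner` in deterministic
#' (tf, partner) lexicographic order, loadable by Cytoscape; the companion
#' TSV carries the joint score and edge p per edge.
#'
#' @param network a `tf_network`.
#' @param path_prefix output prefix; writes `<prefix>.sif` and
#'   `<prefix>_edges.tsv`.
#' @param format only `"sif"` is known.
#' @return Character vector of the files written, invisibly.
#' @export
write_network <- function(network, path_prefix, format = "sif") {
  stopifnot(inherits(network, "tf_network"))
  if (!identical(format, "sif")) stop("unknown network format: ", format)
  e <- network$edges[order(network$edges$tf, network$edges$partner), ,
                     drop = FALSE]
  sif <- file.path(paste0(path_prefix, ".sif"))
  tsv <- file.path(paste0(path_prefix, "_edges.tsv"))
  writeLines(if (nrow(e)) paste(e$tf, "regulates", e$partner, sep = "\t")
             else character(), sif)
  df <- data.frame(tf = e$tf, partner = e$partner,
                   z = formatC(e$z, digits = 15, format = "g"),
                   edge_p = formatC(e$edge_p, digits = 15, format = "g"))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, tsv))
}

#' Read back a network edge TSV written by [write_network()]
#' @param path the `<prefix>_edges.tsv` file.
#' @return data.frame `tf`, `partner`, `z`, `edge_p`.
#' @export
read_network_edges <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write a histology table TSV
#'
#' Columns: `mouse_id`, `group`, `sm22`, `collagen`, `cd68`, `oro`,
#' `burden`; empty cells are missing values.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_histology <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_named_df(tab, c("mouse_id", "group", "sm22", "collagen",
                              "cd68", "oro", "burden"), "histology table")
  tab
}

#' @rdname read_histology
#' @param table data.frame to write.
#' @export
write_histology <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects the stage parameters and the global seed.  Every stochastic
#' stage derives its own seed from `seed` and the stage name via
#' [derive_seed()], so a fixed config reproduces every output byte for byte.
#'
#' @param seed global integer seed.
#' @param fdr_threshold mouse-contrast membership threshold (default 0.30).
#' @param fdr_method `"efron_local"` or `"bh"` for the mouse contrasts.
#' @param knockdown_fdr screen threshold (default 0.1).
#' @param cis_window,ld_window windows in bp (defaults 1 Mb, 200 kb).
#' @param r2_threshold LD proxy threshold (default 0.9).
#' @param esnp_fdr BH threshold of the cis-eSNP rule (default 0.05).
#' @param retain_fraction network retention (default 0.5).
#' @param n_random_sets matched random sets (default 5000).
#' @param alpha nominal GWAS significance (default 0.05).
#' @param maf_min MAF filter for the matched null (default 0.05).
#' @param excluded_samples sample ids dropped before differential expression.
#' @param paths named list of optional input paths (any stage with a path
#'   reads it instead of simulating).
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, fdr_threshold = 0.30,
                       fdr_method = "efron_local", knockdown_fdr = 0.1,
                       cis_window = 1e6, ld_window = 2e5,
                       r2_threshold = 0.9, esnp_fdr = 0.05,
                       retain_fraction = 0.5, n_random_sets = 5000L,
                       alpha = 0.05, maf_min = 0.05,
                       excluded_samples = character(), paths = list()) {
  chk01 <- function(x, nm) if (x <= 0 || x >= 1)
    stop(nm, " must lie in (0, 1)")
  chk01(fdr_threshold, "fdr_threshold"); chk01(knockdown_fdr, "knockdown_fdr")
  chk01(esnp_fdr, "esnp_fdr"); chk01(alpha, "alpha")
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must lie in (0, 1]")
  if (cis_window <= 0 || ld_window <= 0) stop("windows must be positive")
  structure(list(seed = as.integer(seed), fdr_threshold = fdr_threshold,
                 fdr_method = fdr_method, knockdown_fdr = knockdown_fdr,
                 cis_window = cis_window, ld_window = ld_window,
                 r2_threshold = r2_threshold, esnp_fdr = esnp_fdr,
                 retain_fraction = retain_fraction,
                 n_random_sets = as.integer(n_random_sets), alpha = alpha,
                 maf_min = maf_min, excluded_samples = excluded_samples,
                 paths = paths),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys match the
#'   [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}
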