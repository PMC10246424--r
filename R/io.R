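#' Read an expression matrix
#'
#' Reads a genes-by-samples expression matrix from either a dense TSV (first
#' column gene IDs, header row sample IDs) or a MatrixMarket triplet with
#' companion features/barcodes TSVs. IDs must be unique and values
#' non-negative; violations are hard errors naming the offenders.
#'
#' @param path path to the TSV, or to the `.mtx` file for `format = "mtx"`.
#' @param format `"tsv"` (dense) or `"mtx"` (triplet; `features` and
#'   `barcodes` paths default to siblings `features.tsv` / `barcodes.tsv`).
#' @param features,barcodes override companion file paths for MTX input.
#' @return A numeric matrix with gene IDs as rownames and sample (or cell)
#'   IDs as colnames.
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else {
    dir <- dirname(path)
    features <- features %||% file.path(dir, "features.tsv")
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    trip <- read.delim(path, header = FALSE, sep = " ", comment.char = "%",
                       stringsAsFactors = FALSE)
    dims <- as.integer(trip[1L, 1:3])
    trip <- trip[-1L, , drop = FALSE]
    genes <- read.delim(features, header = FALSE)[[1L]]
    cells <- read.delim(barcodes, header = FALSE)[[1L]]
    assert_that(length(genes) == dims[1L] && length(cells) == dims[2L],
                "MTX dimensions disagree with features/barcodes files")
    m <- matrix(0, dims[1L], dims[2L], dimnames = list(genes, cells))
    m[cbind(as.integer(trip[[1L]]), as.integer(trip[[2L]]))] <-
      as.numeric(trip[[3L]])
  }
  validate_expression(m)
}

validate_expression <- function(m) {
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g))
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  if (any(!is.finite(m))) stop("expression matrix has non-finite entries")
  if (any(m < 0)) {
    ij <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression at gene '%s', sample '%s'",
                 rownames(m)[ij[1L]], colnames(m)[ij[2L]]))
  }
  m
}

#' Write an expression matrix as dense TSV
#'
#' Genes as rows, samples as columns; round-trips bit-exactly with
#' [read_expression()] at full double precision.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write single-cell counts as MatrixMarket triplet plus companions
#'
#' @param m genes-by-cells matrix.
#' @param dir output directory; writes `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @export
write_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(m != 0, arr.ind = TRUE)
  con <- file.path(dir, "matrix.mtx")
  lines <- c("%%MatrixMarket matrix coordinate real general",
             paste(nrow(m), ncol(m), nrow(nz)),
             paste(nz[, 1L], nz[, 2L], m[nz]))
  writeLines(lines, con)
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# standard MAF variant-classification vocabulary; others retained but flagged
MAF_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site", "Silent", "Intron", "RNA",
  "IGR", "3'UTR", "5'UTR", "3'Flank", "5'Flank")

NONSYNONYMOUS_CLASSES <- setdiff(
  MAF_CLASSES, c("Silent", "Intron", "RNA", "IGR",
                 "3'UTR", "5'UTR", "3'Flank", "5'Flank"))

#' Read a MAF-style somatic mutation table
#'
#' Requires at least `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`; gene symbols are preserved verbatim (no case
#' folding). Classifications outside the standard MAF vocabulary are retained
#' but flagged in the `nonstandard_class` column.
#'
#' @param path MAF TSV path.
#' @return data.frame with columns `sample_id`, `gene`,
#'   `variant_classification`, `protein_position` (NA when absent) and
#'   `nonstandard_class`.
#' @export
read_maf <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MAF is missing mandatory column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    sample_id = as.character(df$Tumor_Sample_Barcode),
    gene = as.character(df$Hugo_Symbol),
    variant_classification = as.character(df$Variant_Classification),
    protein_position = if ("Protein_position" %in% names(df))
      suppressWarnings(as.integer(df$Protein_position)) else NA_integer_,
    stringsAsFactors = FALSE)
  assert_that(all(nzchar(out$sample_id)) && all(nzchar(out$gene)),
              "MAF contains empty sample or gene strings")
  out$nonstandard_class <- !(out$variant_classification %in% MAF_CLASSES)
  if (any(out$nonstandard_class))
    warning(sum(out$nonstandard_class),
            " rows carry a non-standard Variant_Classification (retained)")
  out
}

#' Write a mutation table in MAF layout
#' @param mut data.frame as returned by [read_maf()] or
#'   [simulate_mutations()].
#' @param path output TSV.
#' @export
write_maf <- function(mut, path) {
  df <- data.frame(Hugo_Symbol = mut$gene,
                   Tumor_Sample_Barcode = mut$sample_id,
                   Variant_Classification = mut$variant_classification,
                   Protein_position = mut$protein_position)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects columns `sample_id`, `time`, `event` plus optional `response` and
#' covariates; `NA` encodes missing values.
#'
#' @param path clinical TSV.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in clinical table")
  if (any(df$time < 0, na.rm = TRUE)) stop("negative survival times")
  if (!all(df$event %in% c(0, 1, NA))) stop("event must be 0/1")
  if ("response" %in% names(df) && !all(df$response %in% c(0, 1, NA)))
    stop("response must be 0/1/NA")
  df
}

#' Write a clinical table
#' @param clin data.frame with at least sample_id, time, event.
#' @param path output TSV.
#' @export
write_clinical <- function(clin, path) {
  write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member genes per line).
#' @return named list of character vectors; empty sets are an error.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line with no member genes: ", parts[1L])
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

config_defaults <- function() {
  list(
    seed = 1L,
    log_level = "info",
    simulation = as.list(simulation_config()),
    signature = list(top_n = 50L, min_fold = 2, min_frac = 0.25,
                     min_cells = 10L, allow_relaxed = FALSE),
    deconvolution = list(method = "nnls", min_overlap = 0.5,
                         quantile_scale = FALSE),
    diversity = list(q = 0.25, scheme = "quartile-extremes",
                     pielou_n = "signature"),
    ssgsea = list(alpha = 0.25, min_overlap = 5L, normalize = FALSE),
    mutations = list(genome_size_mb = 38, min_mutated = 3L,
                     interaction_floor = 5L, top_k = 10L,
                     include_silent = FALSE),
    wgcna = list(soft_power = 8L, min_module_size = 5L, cut_height = 0.99,
                 n_variable_genes = 5000L),
    surrogate = list(n_trees = 500L, train_frac = 0.7, top_k = 15L,
                     r_threshold = 0.75, min_node = 5L, n_permutations = 3L)
  )
}

#' Load and validate a YAML pipeline configuration
#'
#' Missing keys take documented defaults; unknown keys and type violations
#' are hard errors naming the key path. An empty file yields all defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested named list of effective settings.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path) %||% list()
  merge_config(defaults, user, "")
}

merge_config <- function(def, user, prefix) {
  if (!is.list(user)) stop("config section '", prefix, "' must be a mapping")
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    key <- paste0(prefix, k)
    if (is.list(def[[k]]) && !is.list(user[[k]]) && !is.null(user[[k]]))
      stop("config key '", key, "' must be a mapping")
    if (is.list(def[[k]])) {
      def[[k]] <- merge_config(def[[k]], user[[k]] %||% list(),
                               paste0(key, "."))
    } else {
      v <- user[[k]]
      if (is.numeric(def[[k]]) && !is.numeric(v))
        stop("config key '", key, "' must be numeric, got ", class(v)[1L])
      if (is.character(def[[k]]) && !is.character(v))
        stop("config key '", key, "' must be a string")
      if (is.logical(def[[k]]) && !is.logical(v))
        stop("config key '", key, "' must be true/false")
      def[[k]] <- if (is.integer(def[[k]])) as.integer(v) else v
    }
  }
  def
}
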