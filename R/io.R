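# Readers/writers for every on-disk artifact the pipeline consumes or emits.
# All gene identifiers are symbols, upper-cased at ingest.

#' Ordered age-group labels
#'
#' The six decade bins spanning 20-79 years that define the trajectory axis.
#' The first bin is the common reference group for differential expression.
#'
#' @return Character vector of length 6 in trajectory order.
#' @export
age_groups <- function() {
  c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79")
}

#' Validate a gene-by-sample count matrix
#'
#' Checks the invariants every count matrix must satisfy: unique gene and
#' sample identifiers, non-negative integral values, no missing values, and
#' at least 2 genes and 2 samples.
#'
#' @param counts Numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @return The validated matrix, invisibly unchanged apart from upper-cased
#'   gene symbols.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  rownames(counts) <- toupper(rownames(counts))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("count matrix needs at least 2 genes and 2 samples")
  if (anyNA(counts))
    stop("missing values are not permitted in count input")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s' (value %s)",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
                 format(counts[bad[1L, , drop = FALSE]])))
  }
  counts
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene symbols.
#' Duplicate gene rows are collapsed by summation (with a warning); duplicate
#' sample ids are fatal. Values must be non-negative integers.
#'
#' @param path Path to a tab-separated file.
#' @return Validated numeric matrix of counts, genes x samples.
#' @export
read_counts <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(hdr))
    stop("duplicate sample identifiers in header: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("count TSV needs a gene column plus at least 2 samples")
  genes <- toupper(as.character(df[[1L]]))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    nonnum <- which(is.na(suppressWarnings(array(as.numeric(mat), dim(mat)))) & !is.na(mat),
                    arr.ind = TRUE)
    if (nrow(nonnum) > 0L)
      stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                   genes[nonnum[1L, 1L]], colnames(mat)[nonnum[1L, 2L]]))
    mode(mat) <- "numeric"
  }
  colnames(mat) <- hdr
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)
    stop(sprintf("missing count at gene '%s', sample '%s'",
                 genes[idx[1L, 1L]], colnames(mat)[idx[1L, 2L]]))
  }
  bad <- which(mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s' (value %s)",
                 genes[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]],
                 format(mat[bad[1L, , drop = FALSE]])))
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing duplicate gene rows by summation: ",
            paste(dup, collapse = ", "))
    mat <- rowsum(mat, group = genes, reorder = FALSE)
    genes <- rownames(mat)
  } else {
    rownames(mat) <- genes
  }
  validate_counts(mat)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `sex` (male/female), `age_group` (one of
#' [age_groups()]; en-dashes are normalized to hyphens) and `tissue`
#' (vat/liver).
#'
#' @param path Path to a tab-separated file.
#' @param samples Optional character vector of sample ids that must each
#'   appear exactly once (typically `colnames` of a count matrix).
#' @return data.frame with `age_group` as an ordered factor.
#' @export
read_sample_table <- function(path, samples = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_sample_table(df, samples)
}

#' @rdname read_sample_table
#' @param x data.frame to validate in place of a file.
#' @export
validate_sample_table <- function(x, samples = NULL) {
  need <- c("sample_id", "sex", "age_group", "tissue")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample ids in sample table")
  x$sex <- tolower(as.character(x$sex))
  if (!all(x$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  ag <- gsub("–", "-", as.character(x$age_group))
  if (!all(ag %in% age_groups()))
    stop("unknown age group(s): ", paste(unique(ag[!ag %in% age_groups()]), collapse = ", "))
  x$age_group <- factor(ag, levels = age_groups(), ordered = TRUE)
  x$tissue <- tolower(as.character(x$tissue))
  if (!all(x$tissue %in% c("vat", "liver")))
    stop("tissue must be 'vat' or 'liver'")
  if (!is.null(samples)) {
    absent <- setdiff(samples, x$sample_id)
    if (length(absent) > 0L)
      stop("samples missing from sample table: ", paste(utils::head(absent, 5L), collapse = ", "))
  }
  x
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: set name, description, then member genes, tab-separated.
#' The description is discarded; gene symbols are upper-cased and
#' de-duplicated within each set.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short) > 0L)
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(toupper(p[-c(1L, 2L)])))
  names(sets) <- nm
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty)) stop("empty gene set(s): ", paste(nm[empty], collapse = ", "))
  sets
}

#' Read a secretome annotation table
#'
#' TSV with columns `gene` and `secretion_class` (one of secreted_blood,
#' secreted_other, not_secreted). Genes absent from the table default to
#' not_secreted downstream.
#'
#' @param path Path to a tab-separated file.
#' @return data.frame with one row per gene.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "secretion_class") %in% names(df)))
    stop("annotation table needs columns 'gene' and 'secretion_class'")
  df$gene <- toupper(as.character(df$gene))
  if (anyDuplicated(df$gene)) stop("annotation table must have one row per gene")
  ok <- c("secreted_blood", "secreted_other", "not_secreted")
  if (!all(df$secretion_class %in% ok))
    stop("secretion_class must be one of: ", paste(ok, collapse = ", "))
  df[, c("gene", "secretion_class")]
}

#' Read a ligand-receptor interaction table
#'
#' TSV with columns `ligand` and `receptor`; direction is ligand -> receptor.
#' Duplicate pairs are dropped.
#'
#' @param path Path to a tab-separated file.
#' @return data.frame with unique (ligand, receptor) rows.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df)))
    stop("interaction table needs columns 'ligand' and 'receptor'")
  df$ligand <- toupper(as.character(df$ligand))
  df$receptor <- toupper(as.character(df$receptor))
  df <- unique(df[, c("ligand", "receptor")])
  rownames(df) <- NULL
  df
}

#' Read an undirected weighted edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `weight`. Self-loops are dropped with
#' a warning; weights must lie in (0, 1]. Duplicate unordered pairs keep
#' their first occurrence.
#'
#' @param path Path to a tab-separated file.
#' @return data.frame of unique undirected edges.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b", "weight") %in% names(df)))
    stop("edge list needs columns 'gene_a', 'gene_b', 'weight'")
  df$gene_a <- toupper(as.character(df$gene_a))
  df$gene_b <- toupper(as.character(df$gene_b))
  df$weight <- as.numeric(df$weight)
  if (anyNA(df$weight) || any(df$weight <= 0) || any(df$weight > 1))
    stop("edge weights must lie in (0, 1]")
  loops <- df$gene_a == df$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) removed from edge list")
    df <- df[!loops, , drop = FALSE]
  }
  key <- ifelse(df$gene_a < df$gene_b,
                paste(df$gene_a, df$gene_b), paste(df$gene_b, df$gene_a))
  df <- df[!duplicated(key), c("gene_a", "gene_b", "weight")]
  rownames(df) <- NULL
  df
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path Path to a text file.
#' @return Character vector of unique upper-cased symbols.
#' @export
read_gene_list <- function(path) {
  g <- trimws(readLines(path))
  unique(toupper(g[nzchar(g)]))
}

#' Write a result table to TSV
#'
#' Rows are ordered deterministically (by `gene`, then `contrast`, when those
#' columns exist); numeric columns are printed at 6 significant digits so
#' that repeated writes of the same result are byte-identical.
#'
#' @param x data.frame, or a matrix with gene rownames (written with a
#'   leading `gene` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(gene = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop("x must be a data.frame or matrix")
  ord <- NULL
  if ("gene" %in% names(x)) ord <- order(x$gene)
  if (all(c("gene", "contrast") %in% names(x))) ord <- order(x$gene, x$contrast)
  if (!is.null(ord)) x <- x[ord, , drop = FALSE]
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- sprintf("%.6g", x[[j]])
  }
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}
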