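# Domain containers and tabular readers/writers.
#
# An expression matrix is a base numeric matrix (genes x samples) with unique
# rownames (gene ids) and colnames (sample ids); a survival cohort is a
# data.frame with columns sample/time/event; a group design is a data.frame
# with columns sample/label (label in {"sensitive","resistant"}); a signed gene
# list is a named integer vector with values +1/-1; a gene-set collection is a
# named list of character vectors with a "description" attribute per set.

#' Validate (and return) a gene-by-sample expression matrix
#'
#' Enforces the container invariants used throughout the package: a numeric
#' matrix with unique, non-empty gene ids as rownames and unique sample ids as
#' colnames, and every value finite. Values are log-scale expression; missing
#' values are a hard error, never imputed, because downstream within-sample
#' order comparisons would be silently corrupted.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry gene ids as rownames and sample ids as colnames")
  }
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "),
         "; collapse them first with collapse_duplicate_genes()")
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample id(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV/CSV
#'
#' First column holds gene ids, the header row holds sample ids. Duplicate
#' gene rows are an error (use [collapse_duplicate_genes()]); any cell that is
#' not a finite number is an error naming its coordinates.
#'
#' @param path file path.
#' @param sep field separator; tab by default, use `","` for CSV.
#' @return numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path, sep = "\t") {
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene-id column plus >=1 sample column")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "),
         "; collapse them first with collapse_duplicate_genes()")
  }
  vals <- suppressWarnings(
    vapply(seq_along(samples), function(j) as.numeric(raw[[j + 1L]]),
           numeric(length(genes))))
  vals <- matrix(vals, nrow = length(genes),
                 dimnames = list(genes, samples))
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric or missing value '%s' at gene '%s' (row %d), sample '%s' (column %d)",
      raw[bad[1], bad[2] + 1L], genes[bad[1]], bad[1], samples[bad[2]], bad[2] + 1L))
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix as TSV
#'
#' Numbers are written with 17 significant digits so that a write/read round
#' trip reproduces the doubles exactly.
#'
#' @param x numeric matrix (genes x samples).
#' @param path output file path.
#' @param sep field separator.
#' @export
write_expression_matrix <- function(x, path, sep = "\t") {
  validate_expression_matrix(x)
  header <- paste(c("gene", colnames(x)), collapse = sep)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Collapse duplicate gene rows
#'
#' Microarray probe-to-gene annotation often leaves several rows per gene; the
#' pipeline requires one. `max_variance` keeps, per gene, the row with the
#' largest variance across samples (the most informative probe); `mean`
#' averages the rows.
#'
#' @param x numeric matrix whose rownames may repeat.
#' @param policy `"max_variance"` or `"mean"`.
#' @return numeric matrix with unique rownames, original first-appearance order.
#' @export
collapse_duplicate_genes <- function(x, policy = c("max_variance", "mean")) {
  policy <- match.arg(policy)
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1L) {
    stop("need a numeric matrix with >=1 row")
  }
  genes <- unique(rownames(x))
  rows <- lapply(genes, function(g) {
    idx <- which(rownames(x) == g)
    if (length(idx) == 1L) return(x[idx, ])
    sub <- x[idx, , drop = FALSE]
    if (policy == "max_variance") {
      sub[which.max(apply(sub, 1L, var)), ]
    } else {
      colMeans(sub)
    }
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(genes, colnames(x))
  out
}

#' Read a phenotype table (survival cohort plus optional group design)
#'
#' Expects columns `sample`, `time`, `event` and optionally `group`. Times are
#' positive follow-up in months; `event` is 1 for relapse/death, 0 for
#' censoring; `group` labels are `sensitive`/`resistant`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return list with `cohort` (data.frame sample/time/event) and `design`
#'   (data.frame sample/label, or `NULL` when no group column is present).
#' @export
read_phenotype <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  cohort <- data.frame(sample = as.character(tab$sample),
                       time = as.numeric(tab$time),
                       event = as.numeric(tab$event),
                       stringsAsFactors = FALSE)
  validate_cohort(cohort)
  design <- NULL
  if ("group" %in% colnames(tab)) {
    design <- data.frame(sample = cohort$sample,
                         label = as.character(tab$group),
                         stringsAsFactors = FALSE)
    validate_design(design, require_two = FALSE)
  }
  list(cohort = cohort, design = design)
}

#' Write a phenotype table as TSV
#' @param cohort data.frame sample/time/event.
#' @param path output file path.
#' @param design optional data.frame sample/label merged in as a `group` column.
#' @export
write_phenotype <- function(cohort, path, design = NULL) {
  validate_cohort(cohort)
  out <- data.frame(sample = cohort$sample,
                    time = sprintf("%.17g", cohort$time),
                    event = format(as.integer(cohort$event)),
                    stringsAsFactors = FALSE)
  if (!is.null(design)) {
    out$group <- design$label[match(cohort$sample, design$sample)]
  }
  lines <- c(paste(colnames(out), collapse = "\t"),
             apply(out, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a survival cohort data.frame
#'
#' @param cohort data.frame with columns sample/time/event.
#' @param require_event require at least one event (needed by any model fit).
#' @return `cohort`, invisibly, if valid.
#' @export
validate_cohort <- function(cohort, require_event = FALSE) {
  stopifnot(is.data.frame(cohort),
            all(c("sample", "time", "event") %in% colnames(cohort)))
  if (anyDuplicated(cohort$sample)) {
    stop("duplicate sample id(s): ",
         paste(unique(cohort$sample[duplicated(cohort$sample)]), collapse = ", "))
  }
  bad <- !is.finite(cohort$time) | cohort$time <= 0
  if (any(bad)) {
    stop("non-positive or missing follow-up time for sample(s): ",
         paste(cohort$sample[bad], collapse = ", "))
  }
  if (!all(cohort$event %in% c(0, 1))) {
    bad <- !(cohort$event %in% c(0, 1))
    stop("event indicator must be 0/1; offending sample(s): ",
         paste(cohort$sample[bad], collapse = ", "))
  }
  if (require_event && sum(cohort$event) < 1) stop("cohort contains no events")
  invisible(cohort)
}

validate_design <- function(design, require_two = TRUE) {
  stopifnot(is.data.frame(design), all(c("sample", "label") %in% colnames(design)))
  ok <- design$label %in% c("sensitive", "resistant")
  if (!all(ok)) {
    stop("group labels must be 'sensitive' or 'resistant'; got: ",
         paste(unique(design$label[!ok]), collapse = ", "))
  }
  if (require_two) {
    n <- table(factor(design$label, levels = c("sensitive", "resistant")))
    if (any(n < 2)) stop("each group needs >=2 samples; got ",
                         paste(sprintf("%s=%d", names(n), n), collapse = ", "))
  }
  invisible(design)
}

#' Construct a signed gene list
#'
#' @param genes character vector of gene ids (unique).
#' @param signs integer vector of +1/-1 (up/down in resistant, or sign of the
#'   Cox coefficient).
#' @return named integer vector, the package's signed-gene-list container.
#' @export
signed_gene_list <- function(genes, signs) {
  genes <- as.character(genes)
  signs <- as.integer(signs)
  if (length(genes) != length(signs)) stop("genes and signs differ in length")
  if (anyDuplicated(genes)) stop("duplicate gene id(s) in signed list")
  if (!all(signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  setNames(signs, genes)
}

#' Read a signed gene list from a two-column TSV (gene, sign)
#' @param path file path.
#' @export
read_signed_gene_list <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  signed_gene_list(tab[[1]], tab[[2]])
}

#' Write a signed gene list as a two-column TSV
#' @param x named +1/-1 vector.
#' @param path output file path.
#' @export
write_signed_gene_list <- function(x, path) {
  writeLines(c("gene\tsign",
               sprintf("%s\t%d", names(x), as.integer(x))), path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, fields `set id <TAB> description <TAB>
#' gene1 <TAB> gene2 ...`. Duplicate genes within a set are dropped silently
#' with a logged count; a line with fewer than three fields is an error.
#'
#' @param path file path.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no sets: GMT file is empty")
  sets <- list()
  n_dropped <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need set id, description, >=1 gene",
                   i, length(fields)))
    }
    genes <- fields[-(1:2)]
    uniq <- unique(genes)
    n_dropped <- n_dropped + (length(genes) - length(uniq))
    set <- uniq
    attr(set, "description") <- fields[2]
    sets[[fields[1]]] <- set
  }
  if (n_dropped > 0L) {
    log_msg("read_gmt: dropped %d duplicate gene entr%s within sets",
            n_dropped, if (n_dropped == 1L) "y" else "ies")
  }
  sets
}

# Align an expression matrix and a cohort on shared sample ids. Unmatched
# samples on either side are dropped with a logged warning; fewer than two
# shared samples is an error.
align_cohort <- function(expr, cohort) {
  shared <- intersect(colnames(expr), cohort$sample)
  if (length(shared) < 2L) {
    stop("fewer than 2 samples shared between expression matrix and phenotype table")
  }
  n_drop <- (ncol(expr) - length(shared)) + (nrow(cohort) - length(shared))
  if (n_drop > 0L) {
    warning(sprintf("dropping %d sample(s) absent from one of expression/phenotype", n_drop))
  }
  list(expr = expr[, shared, drop = FALSE],
       cohort = cohort[match(shared, cohort$sample), , drop = FALSE])
}
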