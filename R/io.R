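## Readers/writers for the tabular formats the pipeline touches.
## Tables are UTF-8 TSV by default; CSV is accepted via `sep`.
## Missing phenotype cells are empty strings on disk and NA in memory:
## zero is a legal pennation angle and must never be conflated with missing.

NEURON_CLASSES <- c("sensory", "sympathetic", "motor")

PHENOTYPE_FIELDS <- c("wet_weight", "slow_fiber_pct", "muscle_length",
                      "fiber_length", "pennation_angle", "pcsa")

read_table_raw <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "")
}

#' Read a muscle phenotype table
#'
#' A muscle table has one row per muscle with mandatory columns `name`
#' and `wet_weight` (grams, strictly positive) and optional columns
#' `limb`, `tracer_group`, `slow_fiber_pct`, `muscle_length`,
#' `fiber_length`, `pennation_angle`, `pcsa`. Blank cells become `NA`,
#' never zero.
#'
#' @param path Path to a TSV (default) or CSV file with a header row.
#' @param sep Field separator, `"\t"` or `","`.
#' @return A data.frame of muscle records, one per row.
#' @export
read_muscle_table <- function(path, sep = "\t") {
  df <- read_table_raw(path, sep)
  validate_muscle_table(df)
}

#' @rdname read_muscle_table
#' @param muscles A muscle data.frame to validate in memory.
#' @export
validate_muscle_table <- function(muscles) {
  for (col in c("name", "wet_weight")) {
    if (!col %in% names(muscles)) {
      stop("muscle table is missing mandatory column '", col, "'", call. = FALSE)
    }
  }
  muscles$name <- as.character(muscles$name)
  if (anyDuplicated(muscles$name)) {
    stop("duplicated muscle name(s): ",
         paste(unique(muscles$name[duplicated(muscles$name)]), collapse = ", "),
         call. = FALSE)
  }
  muscles$wet_weight <- as.numeric(muscles$wet_weight)
  bad <- which(!is.finite(muscles$wet_weight) | muscles$wet_weight <= 0)
  if (length(bad)) {
    stop("non-positive or missing wet_weight in row(s): ",
         paste(bad, collapse = ", "), " (", paste(muscles$name[bad], collapse = ", "),
         ")", call. = FALSE)
  }
  for (col in setdiff(PHENOTYPE_FIELDS, "wet_weight")) {
    if (col %in% names(muscles)) muscles[[col]] <- as.numeric(muscles[[col]])
  }
  rownames(muscles) <- NULL
  muscles
}

#' @rdname read_muscle_table
#' @export
write_muscle_table <- function(muscles, path, sep = "\t") {
  utils::write.table(muscles, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-segment neuron count table
#'
#' Expects columns `muscle`, `neuron_class`, `segment`, `count`: one row
#' per labeled-neuron count for a (muscle, class, ganglion segment) key.
#' Segment labels are parsed against the canonical C1-S4 vocabulary,
#' counts must be non-negative integers, and duplicate keys are rejected.
#'
#' @inheritParams read_muscle_table
#' @return A data.frame with the four key columns plus `global_index`.
#' @export
read_count_table <- function(path, sep = "\t") {
  df <- read_table_raw(path, sep)
  validate_count_table(df)
}

#' @rdname read_count_table
#' @param counts A count data.frame to validate in memory.
#' @export
validate_count_table <- function(counts) {
  need <- c("muscle", "neuron_class", "segment", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("count table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  counts$muscle <- as.character(counts$muscle)
  counts$neuron_class <- as.character(counts$neuron_class)
  badc <- setdiff(unique(counts$neuron_class), NEURON_CLASSES)
  if (length(badc)) {
    stop("unknown neuron class(es): ", paste(badc, collapse = ", "),
         " (expected ", paste(NEURON_CLASSES, collapse = ", "), ")",
         call. = FALSE)
  }
  seg <- parse_segment(counts$segment)
  counts$segment <- seg$label
  counts$global_index <- seg$global_index
  counts$count <- as.numeric(counts$count)
  bad <- which(!is.finite(counts$count) | counts$count < 0 |
                 counts$count != round(counts$count))
  if (length(bad)) {
    stop("counts must be non-negative integers; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts$count <- as.integer(round(counts$count))
  key <- paste(counts$muscle, counts$neuron_class, counts$segment, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicated (muscle, class, segment) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  rownames(counts) <- NULL
  counts[c(need, "global_index")]
}

#' @rdname read_count_table
#' @export
write_count_table <- function(counts, path, sep = "\t") {
  utils::write.table(counts[c("muscle", "neuron_class", "segment", "count")],
                     path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write a density matrix
#'
#' A density matrix holds mass-normalized neuron counts (neurons per gram
#' of muscle): rows are muscles, columns the fixed class order
#' (`sensory`, `sympathetic`, `motor`). On disk the first column is
#' `muscle`; extra annotation columns are ignored on read.
#'
#' @inheritParams read_muscle_table
#' @return A numeric matrix with muscle rownames and the three class columns.
#' @export
read_density_matrix <- function(path, sep = "\t") {
  df <- read_table_raw(path, sep)
  miss <- setdiff(c("muscle", NEURON_CLASSES), names(df))
  if (length(miss)) {
    stop("density table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(df[NEURON_CLASSES])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(df$muscle)
  validate_density_matrix(X)
}

#' @rdname read_density_matrix
#' @param X A density matrix to validate in memory.
#' @export
validate_density_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(rownames(X))) stop("density matrix needs muscle rownames", call. = FALSE)
  if (!identical(colnames(X), NEURON_CLASSES)) {
    if (all(NEURON_CLASSES %in% colnames(X))) {
      X <- X[, NEURON_CLASSES, drop = FALSE]
    } else {
      stop("density matrix needs columns sensory, sympathetic, motor", call. = FALSE)
    }
  }
  if (anyDuplicated(rownames(X))) stop("duplicated muscle rownames", call. = FALSE)
  if (any(!is.finite(X)) || any(X < 0)) {
    stop("densities must be finite and non-negative", call. = FALSE)
  }
  X
}

#' @rdname read_density_matrix
#' @export
write_density_matrix <- function(X, path, sep = "\t") {
  X <- validate_density_matrix(X)
  df <- data.frame(muscle = rownames(X), as.data.frame(X),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `id<TAB>description<TAB>member1<TAB>member2...`. Member symbols are
#' upper-cased (the same convention expression datasets use) and
#' deduplicated; sets left without members are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list; each element is `list(description=, members=)`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields", call. = FALSE)
    }
    members <- unique(toupper(trimws(f[-(1:2)])))
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("GMT line ", i, " (", f[1], ") has no members; dropped")
      next
    }
    sets[[f[1]]] <- list(description = f[2], members = members)
  }
  sets
}

#' @rdname read_gene_sets
#' @param sets A gene-set collection as returned by `read_gene_sets()`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$description, sets[[id]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Expects columns `sample`, `group`, `gene`, `ct` with finite positive
#' cycle-threshold values. Technical replicates (repeated
#' (sample, gene) rows) are allowed and averaged downstream.
#'
#' @inheritParams read_muscle_table
#' @return A data.frame with the four columns.
#' @export
read_ct_table <- function(path, sep = "\t") {
  df <- read_table_raw(path, sep)
  miss <- setdiff(c("sample", "group", "gene", "ct"), names(df))
  if (length(miss)) {
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct) | df$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  df[c("sample", "group", "gene", "ct")]
}

#' @rdname read_ct_table
#' @param ct A Ct data.frame.
#' @export
write_ct_table <- function(ct, path, sep = "\t") {
  utils::write.table(ct, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
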