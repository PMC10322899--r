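# Study-level containers, flat-file readers/writers, clinical dictionary
# validation, gene/alias harmonization and Gleason grade grouping.

GRADE_GROUPS <- c("<=6", "7", ">=8")
SAMPLE_TYPES <- c("primary", "metastatic", "normal", "BPH", "atrophic")
VARIANT_CLASSES <- c("Silent", "Missense_Mutation", "Nonsense_Mutation",
                     "Frame_Shift_Ins", "Frame_Shift_Del", "Splice_Site",
                     "Other")
MUTATION_STATUS <- c("matched_normal", "tumor_only")

CLINICAL_COLUMNS <- c("sample_id", "patient_id", "sample_type", "grade_group",
                      "gleason_primary", "gleason_secondary", "gleason_sum",
                      "isup", "bcr_event", "time_to_bcr", "os_event",
                      "time_to_os")

#' Construct an expression matrix
#'
#' A genes-by-samples numeric matrix of (typically log2-scale) expression
#' values with unique sample ids. Duplicate gene rows are allowed on input;
#' [harmonize_genes()] collapses them.
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param scale_tag `"log2"` or `"unknown"`.
#' @return the matrix with a `scale_tag` attribute, class `expr_matrix`.
#' @export
expression_matrix <- function(values, scale_tag = c("log2", "unknown")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires gene rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(is.infinite(values)))
    stop("expression values must be finite or missing")
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", class(values)))
}

#' Construct a copy-number call matrix
#'
#' Genes-by-samples integer matrix of GISTIC-style discretized calls:
#' -2 deep loss, -1 shallow loss, 0 diploid, 1 gain, 2 amplification.
#'
#' @param calls integer matrix; entries in `-2:2` or `NA`.
#' @return matrix of class `cna_matrix`.
#' @export
cna_matrix <- function(calls) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("copy-number matrix requires gene rownames and sample colnames")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate sample ids in copy-number matrix")
  vals <- calls[!is.na(calls)]
  if (any(vals != round(vals)))
    stop("copy-number calls must be integers")
  if (any(vals < -2 | vals > 2))
    stop("copy-number calls outside {-2,...,2}: ",
         paste(unique(vals[vals < -2 | vals > 2]), collapse = ", "))
  storage.mode(calls) <- "integer"
  structure(calls, class = c("cna_matrix", class(calls)))
}

#' Construct a mutation table
#'
#' Long-format somatic mutation calls. `variant_class` outside the controlled
#' vocabulary is recoded to `"Other"` with a warning; `mutation_status`
#' records whether calls used a matched normal.
#'
#' @param sample_id,gene_symbol character vectors.
#' @param variant_class character; see `VARIANT_CLASSES` vocabulary.
#' @param mutation_status `"matched_normal"` or `"tumor_only"`.
#' @return data.frame of class `mutation_table`.
#' @export
mutation_table <- function(sample_id, gene_symbol, variant_class,
                           mutation_status = "matched_normal") {
  sample_id <- as.character(sample_id)
  gene_symbol <- as.character(gene_symbol)
  variant_class <- as.character(variant_class)
  n <- length(sample_id)
  mutation_status <- rep_len(as.character(mutation_status), n)
  if (length(gene_symbol) != n || length(variant_class) != n)
    stop("mutation table columns must have equal length")
  if (any(!nzchar(sample_id)) || any(!nzchar(gene_symbol)))
    stop("sample_id and gene_symbol must be nonempty")
  unknown <- !(variant_class %in% VARIANT_CLASSES)
  if (any(unknown)) {
    warning("unknown Variant_Classification recoded to Other: ",
            paste(unique(variant_class[unknown]), collapse = ", "))
    variant_class[unknown] <- "Other"
  }
  bad_status <- !(mutation_status %in% MUTATION_STATUS)
  if (any(bad_status))
    stop("mutation_status must be one of: ",
         paste(MUTATION_STATUS, collapse = ", "))
  structure(data.frame(sample_id = sample_id, gene_symbol = gene_symbol,
                       variant_class = variant_class,
                       mutation_status = mutation_status,
                       stringsAsFactors = FALSE),
            class = c("mutation_table", "data.frame"))
}

#' Construct a gene/alias dictionary
#'
#' Maps alias symbols to canonical (HGNC-style) symbols. An alias mapping to
#' more than one canonical symbol must carry a priority flag on exactly one
#' of its rows, or rows bearing it are dropped during harmonization.
#'
#' @param canonical,alias character vectors of equal length.
#' @param priority logical; marks the preferred target of an ambiguous alias.
#' @return data.frame of class `gene_dictionary`.
#' @export
gene_dictionary <- function(canonical = character(), alias = character(),
                            priority = FALSE) {
  canonical <- as.character(canonical)
  alias <- as.character(alias)
  priority <- rep_len(as.logical(priority), length(canonical))
  if (length(alias) != length(canonical))
    stop("canonical and alias must have equal length")
  if (any(!nzchar(canonical)))
    stop("canonical symbols must be nonempty")
  # a canonical symbol used as another symbol's alias needs a priority flag
  clash <- alias %in% canonical & alias != canonical & !priority
  if (any(clash))
    stop("canonical symbol(s) appear as aliases without a priority flag: ",
         paste(unique(alias[clash]), collapse = ", "))
  structure(data.frame(canonical = canonical, alias = alias,
                       priority = priority, stringsAsFactors = FALSE),
            class = c("gene_dictionary", "data.frame"))
}

#' Construct a clinical table conforming to the data dictionary
#'
#' Columns follow the shared data dictionary: identifiers, sample type,
#' Gleason fields (grade group, primary/secondary/sum, ISUP group) and the
#' biochemical-recurrence and overall-survival endpoints in months. Missing
#' optional fields are `NA`. Use [validate_clinical()] to audit a parsed
#' table without erroring.
#'
#' @param df data.frame with at least `sample_id`, `patient_id`,
#'   `sample_type`; remaining dictionary columns are added as `NA` when
#'   absent.
#' @return data.frame of class `clinical_table`.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "sample_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "))
  for (col in setdiff(CLINICAL_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[CLINICAL_COLUMNS]
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  df$sample_type <- as.character(df$sample_type)
  df$grade_group <- as.character(df$grade_group)
  for (col in c("gleason_primary", "gleason_secondary", "gleason_sum", "isup",
                "bcr_event", "os_event"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("time_to_bcr", "time_to_os"))
    df[[col]] <- as.numeric(df[[col]])
  structure(df, class = c("clinical_table", "data.frame"))
}

# ---- readers / writers -----------------------------------------------------

read_matrix_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2) stop("matrix file needs a gene column and >=1 sample")
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s) in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- fields[-1]
  ncol_expect <- length(header)
  ragged <- vapply(body, length, integer(1)) != ncol_expect
  if (any(ragged))
    stop("ragged row(s) at line ", paste(which(ragged) + 1L, collapse = ", "))
  genes <- vapply(body, `[[`, character(1), 1L)
  cells <- vapply(body, function(f) f[-1], character(length(samples)))
  cells <- matrix(cells, nrow = length(samples))  # samples x genes
  missing <- cells == "NA" | cells == ""
  num <- suppressWarnings(as.numeric(cells))
  bad <- is.na(num) & !missing
  if (any(bad))
    stop("non-numeric cell value(s): ",
         paste(unique(cells[bad]), collapse = ", "))
  num[missing] <- NA_real_
  m <- t(matrix(num, nrow = length(samples),
                dimnames = list(samples, genes)))
  m
}

#' Read a gene-by-sample expression TSV
#'
#' First column holds gene symbols, header row holds sample ids; the missing
#' token is a literal `NA` or an empty cell (case-sensitive).
#'
#' @param path file path.
#' @param scale_tag declared scale of the stored values.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale_tag = c("log2", "unknown")) {
  expression_matrix(read_matrix_tsv(path), scale_tag = match.arg(scale_tag))
}

#' Write an expression matrix as TSV
#' @param x matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  write_matrix_tsv(x, path)
}

write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GISTIC-style thresholded copy-number TSV
#'
#' Same layout as the expression TSV; every non-missing entry must be an
#' integer call in `-2:2` (-2 deep loss, -1 shallow loss, 0 diploid, 1 gain,
#' 2 amplification).
#'
#' @param path file path.
#' @return a [cna_matrix()].
#' @export
read_gistic_matrix <- function(path) {
  m <- read_matrix_tsv(path)
  vals <- m[!is.na(m)]
  if (any(vals != round(vals)))
    stop("non-integer copy-number call(s): ",
         paste(unique(vals[vals != round(vals)]), collapse = ", "))
  cna_matrix(m)
}

#' Write a copy-number matrix as TSV
#' @param x [cna_matrix()].
#' @param path output path.
#' @export
write_gistic_matrix <- function(x, path) write_matrix_tsv(x, path)

#' Read a MAF mutation file
#'
#' Requires the standard `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification` columns; an optional `Mutation_Status` column is
#' mapped onto `{matched_normal, tumor_only}` (MAF's conventional "Somatic"
#' counts as matched_normal). Unknown variant classes are recoded to `Other`
#' with a warning.
#'
#' @param path file path.
#' @return a [mutation_table()].
#' @export
read_maf <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MAF missing required column(s): ", paste(miss, collapse = ", "))
  status <- if ("Mutation_Status" %in% names(df)) {
    s <- tolower(df$Mutation_Status)
    ifelse(s %in% c("tumor_only", "tumour_only", "unmatched"),
           "tumor_only", "matched_normal")
  } else "matched_normal"
  mutation_table(sample_id = df$Tumor_Sample_Barcode,
                 gene_symbol = df$Hugo_Symbol,
                 variant_class = df$Variant_Classification,
                 mutation_status = status)
}

#' Write a mutation table as a MAF file
#' @param x [mutation_table()].
#' @param path output path.
#' @export
write_maf <- function(x, path) {
  out <- data.frame(Hugo_Symbol = x$gene_symbol,
                    Tumor_Sample_Barcode = x$sample_id,
                    Variant_Classification = x$variant_class,
                    Mutation_Status = x$mutation_status,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clinical TSV conforming to the data dictionary
#' @param path file path.
#' @return a [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  clinical_table(df)
}

#' Write a clinical table as TSV
#' @param x [clinical_table()].
#' @param path output path.
#' @export
write_clinical <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene alias dictionary TSV
#'
#' Columns `canonical`, `alias` and optional logical `priority`.
#' @param path file path.
#' @return a [gene_dictionary()].
#' @export
read_gene_dictionary <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("canonical", "alias") %in% names(df)))
    stop("dictionary needs 'canonical' and 'alias' columns")
  pr <- if ("priority" %in% names(df)) as.logical(df$priority) else FALSE
  gene_dictionary(df$canonical, df$alias, pr)
}

# ---- clinical validation ---------------------------------------------------

#' Validate a clinical table against the data dictionary
#'
#' Violations are reported as data, never thrown: a fully conformant table
#' yields an empty report. Case-only mismatches of controlled vocabularies
#' (e.g. `"Primary"` for `"primary"`) get a normalization hint.
#'
#' @param table a [clinical_table()] (or coercible data.frame).
#' @return a `validation_report`: data.frame of
#'   `(field, sample_id, rule_violated, message)` with per-sample-type counts
#'   in `attr(, "counts")`.
#' @export
validate_clinical <- function(table) {
  if (!inherits(table, "clinical_table")) table <- clinical_table(table)
  v <- list()
  note <- function(field, sample_id, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(field = field, sample_id = sample_id,
                                       rule_violated = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  dup <- unique(table$sample_id[duplicated(table$sample_id)])
  for (d in dup) note("sample_id", d, "unique", "duplicated sample_id")
  check_vocab <- function(field, allowed) {
    x <- table[[field]]
    for (i in which(!is.na(x) & !(x %in% allowed))) {
      hint <- if (tolower(x[i]) %in% tolower(allowed))
        paste0("; did you mean '", allowed[match(tolower(x[i]),
                                                 tolower(allowed))], "'?")
      else ""
      note(field, table$sample_id[i], "controlled_vocabulary",
           paste0("value '", x[i], "' not in {",
                  paste(allowed, collapse = ", "), "}", hint))
    }
  }
  check_vocab("sample_type", SAMPLE_TYPES)
  check_vocab("grade_group", GRADE_GROUPS)
  for (field in c("bcr_event", "os_event")) {
    x <- table[[field]]
    for (i in which(!is.na(x) & !(x %in% c(0L, 1L))))
      note(field, table$sample_id[i], "binary_event",
           paste0("event indicator must be 0 or 1, got ", x[i]))
  }
  for (field in c("time_to_bcr", "time_to_os")) {
    x <- table[[field]]
    for (i in which(!is.na(x) & x < 0))
      note(field, table$sample_id[i], "nonnegative_time",
           paste0("follow-up time must be >= 0 months, got ", x[i]))
  }
  x <- table$isup
  for (i in which(!is.na(x) & !(x %in% 1:5)))
    note("isup", table$sample_id[i], "isup_range",
         paste0("ISUP group must be in 1..5, got ", x[i]))
  x <- table$gleason_sum
  for (i in which(!is.na(x) & (x < 2 | x > 10)))
    note("gleason_sum", table$sample_id[i], "gleason_range",
         paste0("Gleason sum must be in 2..10, got ", x[i]))
  all3 <- !is.na(table$gleason_primary) & !is.na(table$gleason_secondary) &
    !is.na(table$gleason_sum)
  for (i in which(all3 & table$gleason_primary + table$gleason_secondary !=
                    table$gleason_sum))
    note("gleason_sum", table$sample_id[i], "gleason_consistency",
         "gleason_sum differs from gleason_primary + gleason_secondary")
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(field = character(), sample_id = character(),
               rule_violated = character(), message = character(),
               stringsAsFactors = FALSE)
  counts <- table(factor(table$sample_type, levels = SAMPLE_TYPES))
  structure(violations, counts = as.list(counts),
            class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("clinical table conforms to the data dictionary (0 violations)\n")
  } else {
    cat(nrow(x), "data-dictionary violation(s):\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

# ---- harmonization ---------------------------------------------------------

#' Harmonize gene symbols of an expression matrix
#'
#' Row symbols known as aliases are renamed to their canonical symbol; rows
#' sharing a canonical symbol are collapsed (`mean` averages them,
#' `max_variance` keeps the most variable row); symbols unknown to the
#' dictionary are kept verbatim and logged; an alias resolving to more than
#' one canonical symbol with no priority flag is dropped and logged. The
#' operation is idempotent.
#'
#' @param matrix an [expression_matrix()].
#' @param dict a [gene_dictionary()].
#' @param collapse_rule `"mean"` or `"max_variance"`.
#' @return list with `matrix` (harmonized [expression_matrix()]) and `log`
#'   (data.frame of `(symbol, action, target)`).
#' @export
harmonize_genes <- function(matrix, dict,
                            collapse_rule = c("mean", "max_variance")) {
  collapse_rule <- match.arg(collapse_rule)
  stopifnot(inherits(dict, "gene_dictionary"))
  scale_tag <- attr(matrix, "scale_tag") %||% "unknown"
  genes <- rownames(matrix)
  log <- list()
  add_log <- function(symbol, action, target = NA_character_) {
    log[[length(log) + 1L]] <<- data.frame(symbol = symbol, action = action,
                                           target = target,
                                           stringsAsFactors = FALSE)
  }
  resolve <- function(s) {
    hits <- dict[dict$alias == s, , drop = FALSE]
    targets <- unique(hits$canonical)
    if (s %in% dict$canonical) targets <- unique(c(targets, s))
    targets <- setdiff(targets, character(0))
    if (length(targets) == 0L) {
      add_log(s, "unknown_kept")
      return(s)
    }
    if (length(targets) == 1L) {
      if (targets != s) add_log(s, "alias_renamed", targets)
      return(targets)
    }
    pri <- unique(hits$canonical[hits$priority])
    if (length(pri) == 1L) {
      add_log(s, "priority_renamed", pri)
      return(pri)
    }
    add_log(s, "ambiguous_dropped")
    NA_character_
  }
  mapped <- unname(vapply(genes, resolve, character(1)))
  keep <- !is.na(mapped)
  m <- matrix[keep, , drop = FALSE]
  mapped <- mapped[keep]
  if (anyDuplicated(mapped)) {
    dup_syms <- unique(mapped[duplicated(mapped)])
    rows <- lapply(unique(mapped), function(g) {
      idx <- which(mapped == g)
      if (length(idx) == 1L) return(m[idx, ])
      add_log(g, paste0("collapsed_", collapse_rule))
      sub <- m[idx, , drop = FALSE]
      if (collapse_rule == "mean") {
        colMeans(sub, na.rm = TRUE)
      } else {
        vars <- apply(sub, 1L, var, na.rm = TRUE)
        sub[which.max(vars), ]
      }
    })
    m <- do.call(rbind, rows)
    rownames(m) <- unique(mapped)
    m[is.nan(m)] <- NA_real_
  } else {
    rownames(m) <- mapped
  }
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(symbol = character(), action = character(),
               target = character(), stringsAsFactors = FALSE)
  list(matrix = expression_matrix(m, scale_tag = scale_tag), log = log_df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Gleason grouping ------------------------------------------------------

#' Map Gleason information to a grade group
#'
#' Resolves whatever Gleason detail a study reports to the shared grade
#' groups `<=6`, `7`, `>=8`. Precedence: reported sum, then
#' primary+secondary, then ISUP group (1 -> `<=6`, 2-3 -> `7`,
#' 4-5 -> `>=8`). All inputs missing yields `NA`, not an error.
#'
#' @param primary,secondary,sum integer Gleason patterns / sum (or `NA`).
#' @param isup ISUP grade group 1..5 (or `NA`).
#' @return character grade group or `NA`. Vectorized over inputs.
#' @export
map_gleason <- function(primary = NA, secondary = NA, sum = NA, isup = NA) {
  n <- max(length(primary), length(secondary), length(sum), length(isup))
  primary <- rep_len(as.integer(primary), n)
  secondary <- rep_len(as.integer(secondary), n)
  sum <- rep_len(as.integer(sum), n)
  isup <- rep_len(as.integer(isup), n)
  eff <- ifelse(!is.na(sum), sum,
                ifelse(!is.na(primary) & !is.na(secondary),
                       primary + secondary, NA_integer_))
  if (any(!is.na(eff) & (eff < 2L | eff > 10L)))
    stop("Gleason sum outside 2..10: ",
         paste(unique(eff[!is.na(eff) & (eff < 2L | eff > 10L)]),
               collapse = ", "))
  if (any(!is.na(isup) & !(isup %in% 1:5)))
    stop("ISUP group outside 1..5")
  out <- rep(NA_character_, n)
  out[!is.na(eff) & eff <= 6L] <- "<=6"
  out[!is.na(eff) & eff == 7L] <- "7"
  out[!is.na(eff) & eff >= 8L] <- ">=8"
  use_isup <- is.na(out) & !is.na(isup)
  out[use_isup & isup == 1L] <- "<=6"
  out[use_isup & isup %in% 2:3] <- "7"
  out[use_isup & isup %in% 4:5] <- ">=8"
  out
}

# ---- study bundle ----------------------------------------------------------

#' Assemble a study bundle
#'
#' Binds a study's assays to its clinical table under one sample namespace:
#' every assay sample must appear in the clinical table and at least one
#' assay must be present.
#'
#' @param name study name.
#' @param expression optional [expression_matrix()].
#' @param cna optional [cna_matrix()].
#' @param mutations optional [mutation_table()].
#' @param clinical a [clinical_table()].
#' @return list of class `study_bundle`.
#' @export
build_study <- function(name, expression = NULL, cna = NULL,
                        mutations = NULL, clinical) {
  if (!inherits(clinical, "clinical_table")) clinical <- clinical_table(clinical)
  if (is.null(expression) && is.null(cna) && is.null(mutations))
    stop("study bundle needs at least one assay")
  assay_samples <- list(
    gex = if (!is.null(expression)) colnames(expression),
    cna = if (!is.null(cna)) colnames(cna),
    mut = if (!is.null(mutations)) unique(mutations$sample_id))
  for (a in names(assay_samples)) {
    s <- assay_samples[[a]]
    orphan <- setdiff(s, clinical$sample_id)
    if (length(orphan))
      stop("assay '", a, "' sample(s) absent from clinical table: ",
           paste(orphan, collapse = ", "))
  }
  structure(list(name = name, expression = expression, cna = cna,
                 mutations = mutations, clinical = clinical),
            class = "study_bundle")
}

#' Per-assay and per-sample-type counts of a study bundle
#' @param bundle a `study_bundle`.
#' @return named list of counts.
#' @export
study_counts <- function(bundle) {
  stopifnot(inherits(bundle, "study_bundle"))
  counts <- list()
  if (!is.null(bundle$expression)) counts$gex <- ncol(bundle$expression)
  if (!is.null(bundle$cna)) counts$cna <- ncol(bundle$cna)
  if (!is.null(bundle$mutations))
    counts$mut <- length(unique(bundle$mutations$sample_id))
  tab <- table(factor(bundle$clinical$sample_type, levels = SAMPLE_TYPES))
  c(counts, as.list(tab[tab > 0]))
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("study bundle '", x$name, "'\n", sep = "")
  cnt <- study_counts(x)
  cat("  ", paste(names(cnt), unlist(cnt), sep = ": ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a study bundle's flat files into a directory
#'
#' Emits `expression.tsv`, `cna.tsv`, `mutations.maf` and `clinical.tsv`
#' (absent assays are skipped).
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$expression))
    write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  if (!is.null(bundle$cna))
    write_gistic_matrix(bundle$cna, file.path(dir, "cna.tsv"))
  if (!is.null(bundle$mutations))
    write_maf(bundle$mutations, file.path(dir, "mutations.maf"))
  write_clinical(bundle$clinical, file.path(dir, "clinical.tsv"))
  invisible(dir)
}

#' Read a study bundle written by [write_study_bundle()]
#' @param name study name.
#' @param dir directory containing the flat files.
#' @return a `study_bundle`.
#' @export
read_study_bundle <- function(name, dir) {
  p <- function(f) file.path(dir, f)
  build_study(
    name = name,
    expression = if (file.exists(p("expression.tsv")))
      read_expression(p("expression.tsv")),
    cna = if (file.exists(p("cna.tsv"))) read_gistic_matrix(p("cna.tsv")),
    mutations = if (file.exists(p("mutations.maf"))) read_maf(p("mutations.maf")),
    clinical = read_clinical(p("clinical.tsv")))
}
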