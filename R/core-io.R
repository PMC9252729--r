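#' Construct a sequence set
#'
#' A sequence set is a tibble with columns `id`, `seq` and `label` and a
#' `kind` attribute (`"protein"`, `"dna"` or `"rna"`). It is the input to all
#' sequence descriptor calculations.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of sequences (uppercased on construction).
#' @param kind one of `"protein"`, `"dna"`, `"rna"`.
#' @param label optional per-sequence category labels (`NA` = unlabelled).
#' @param ambiguity `"strict"` rejects ambiguous characters (X/B/Z/U for
#'   protein, IUPAC degenerate codes for nucleic acids); `"drop"` removes them
#'   so composition denominators only count canonical residues.
#' @param transliterate if `TRUE` (default), T is rewritten to U for RNA and
#'   U to T for DNA before validation.
#' @return a tibble of class `omega_seqs`.
#' @export
seq_set <- function(id, seq, kind, label = NULL,
                    ambiguity = c("strict", "drop"), transliterate = TRUE) {
  kind <- match.arg(kind, c("protein", "dna", "rna"))
  ambiguity <- match.arg(ambiguity)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1]])
  if (any(!nzchar(seq))) stop("empty sequence for id ", id[!nzchar(seq)][[1]])
  if (transliterate) {
    if (kind == "rna") seq <- gsub("T", "U", seq, fixed = TRUE)
    if (kind == "dna") seq <- gsub("U", "T", seq, fixed = TRUE)
  }
  alpha <- ALPHABETS[[kind]]
  amb <- AMBIGUITY[[kind]]
  seq <- vapply(seq_along(seq), function(i) {
    s <- seq[[i]]
    ch <- strsplit(s, "")[[1]]
    bad <- !(ch %in% alpha)
    if (any(bad)) {
      offender <- ch[bad]
      amb_ok <- offender %in% amb
      if (ambiguity == "strict" || !all(amb_ok)) {
        pos <- which(bad)[[1]]
        stop("invalid character '", ch[[pos]], "' at position ", pos,
             " in sequence ", id[[i]], call. = FALSE)
      }
      s <- paste0(ch[!bad], collapse = "")
      if (!nzchar(s)) stop("sequence ", id[[i]], " empty after dropping ambiguity")
    }
    s
  }, character(1))
  if (is.null(label)) label <- rep(NA_character_, length(id))
  out <- tibble::tibble(id = id, seq = seq, label = as.character(label))
  attr(out, "kind") <- kind
  class(out) <- c("omega_seqs", class(out))
  out
}

#' @export
print.omega_seqs <- function(x, ...) {
  cat("<sequence set: ", nrow(x), " ", attr(x, "kind"), " sequence(s)>\n", sep = "")
  NextMethod()
}

seq_kind <- function(x) attr(x, "kind")

#' Read a FASTA file into a sequence set
#'
#' Headers follow the `>id|label` dialect: text up to the first whitespace is
#' the record name; if it contains a pipe, the part after the last pipe is the
#' class label. An empty file yields an empty sequence set.
#'
#' @param path FASTA file.
#' @inheritParams seq_set
#' @return an [seq_set()] tibble.
#' @export
read_fasta <- function(path, kind, ambiguity = c("strict", "drop"),
                       transliterate = TRUE) {
  kind <- match.arg(kind, c("protein", "dna", "rna"))
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    out <- tibble::tibble(id = character(), seq = character(), label = character())
    attr(out, "kind") <- kind
    class(out) <- c("omega_seqs", class(out))
    return(out)
  }
  header <- sub("\\s.*$", "", names(ss))
  has_label <- grepl("|", header, fixed = TRUE)
  id <- ifelse(has_label, sub("\\|[^|]*$", "", header), header)
  label <- ifelse(has_label, sub("^.*\\|", "", header), NA_character_)
  seq_set(id, as.character(ss), kind, label,
          ambiguity = match.arg(ambiguity), transliterate = transliterate)
}

#' Write a sequence set as FASTA
#' @param seqs an [seq_set()] tibble.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  hdr <- ifelse(is.na(seqs$label), seqs$id, paste0(seqs$id, "|", seqs$label))
  writeLines(paste0(">", hdr, "\n", seqs$seq), path)
  invisible(path)
}

# --- feature matrices --------------------------------------------------------

#' Build a feature tibble
#'
#' The universal exchange object: a tibble whose first column is `id`,
#' followed by an optional `label` column, then numeric feature columns.
#'
#' @param values numeric matrix (rows = samples).
#' @param ids sample identifiers.
#' @param labels optional labels.
#' @return tibble.
#' @export
feature_tbl <- function(values, ids, labels = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  stopifnot(length(ids) == nrow(values))
  if (anyDuplicated(colnames(values))) {
    colnames(values) <- make.unique(colnames(values), sep = ".")
  }
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(ids)), out)
  if (!is.null(labels) && !all(is.na(labels))) {
    out <- dplyr::bind_cols(out[, 1, drop = FALSE],
                            tibble::tibble(label = as.character(labels)),
                            out[, -1, drop = FALSE])
  }
  out
}

#' Extract the numeric feature block of a feature tibble
#' @param tbl feature tibble.
#' @return numeric matrix with sample ids as rownames.
#' @export
feature_values <- function(tbl) {
  keep <- setdiff(names(tbl), c("id", "label"))
  m <- as.matrix(tbl[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$id
  m
}

feature_labels <- function(tbl) if ("label" %in% names(tbl)) tbl$label else NULL

#' Write a feature tibble to disk
#'
#' Four formats: `csv` / `tsv` (header of feature names, first column the
#' sample id, `label` column retained when present), `svm_light` (sparse
#' `label index:value` lines, 1-based feature indices, zeros omitted) and
#' `arff` (numeric attributes, nominal `class` attribute last when labels
#' exist; relation name = file stem).
#'
#' @param tbl feature tibble.
#' @param path output file.
#' @param format one of `csv`, `tsv`, `svm_light`, `arff`.
#' @export
write_features <- function(tbl, path, format = c("csv", "tsv", "svm_light", "arff")) {
  format <- match.arg(format)
  m <- feature_values(tbl)
  labels <- feature_labels(tbl)
  switch(format,
    csv = utils::write.csv(as.data.frame(tbl), path, row.names = FALSE, quote = FALSE),
    tsv = utils::write.table(as.data.frame(tbl), path, row.names = FALSE,
                             quote = FALSE, sep = "\t"),
    svm_light = {
      lab <- if (is.null(labels)) rep(0, nrow(m)) else labels
      lines <- vapply(seq_len(nrow(m)), function(i) {
        nz <- which(m[i, ] != 0)
        paste(c(lab[[i]], sprintf("%d:%.10g", nz, m[i, nz])), collapse = " ")
      }, character(1))
      writeLines(lines, path)
    },
    arff = {
      rel <- sub("\\.[^.]*$", "", basename(path))
      con <- file(path, "w"); on.exit(close(con))
      writeLines(paste0("@RELATION ", rel), con)
      writeLines(paste0("@ATTRIBUTE ", make.names(colnames(m)), " NUMERIC"), con)
      if (!is.null(labels)) {
        lv <- sort(unique(labels))
        writeLines(paste0("@ATTRIBUTE class {", paste(lv, collapse = ","), "}"), con)
      }
      writeLines("@DATA", con)
      body <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = ","))
      if (!is.null(labels)) body <- paste(body, labels, sep = ",")
      writeLines(body, con)
    }
  )
  invisible(path)
}

#' Read a feature tibble written by [write_features()] (csv/tsv only)
#' @param path input file.
#' @param format `csv` or `tsv`.
#' @export
read_features <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- utils::read.table(path, header = TRUE, sep = if (format == "csv") "," else "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(df)) df$label else NULL
  keep <- setdiff(names(df), c("id", "label"))
  feature_tbl(as.matrix(df[, keep, drop = FALSE]), df$id, labels)
}

#' Run configuration
#'
#' Reads and validates the JSON run configuration shared by the command-line
#' schemes. Unknown top-level keys are rejected.
#'
#' @param path JSON file.
#' @return a validated named list of class `omega_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

CONFIG_KEYS <- c("scheme", "input", "kind", "descriptors", "parameters",
                 "output", "format", "seed", "analysis", "plot", "targets",
                 "ambiguity")

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  schemes <- c("iProtein", "iDNA", "iRNA", "iStructure", "iLigand",
               "iAnalysis", "iPlot")
  if (is.null(cfg$scheme) || !cfg$scheme %in% schemes) {
    stop("scheme must be one of: ", paste(schemes, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  kind <- switch(cfg$scheme, iProtein = "protein", iDNA = "dna", iRNA = "rna",
                 iStructure = "structure", iLigand = "ligand", NULL)
  if (!is.null(kind) && length(cfg$descriptors)) {
    known <- list_descriptors(kind)$name
    bad <- setdiff(cfg$descriptors, known)
    if (length(bad)) {
      stop("descriptor(s) not valid for scheme ", cfg$scheme, ": ",
           paste(bad, collapse = ", "))
    }
  }
  cfg$.kind <- kind
  class(cfg) <- "omega_config"
  cfg
}
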