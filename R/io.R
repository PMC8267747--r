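#' Read and write compound datasets
#'
#' Datasets are CSV files with a mandatory header and columns `id`,
#' `dock_score` and optionally `label` (0/1, 1 = binder). An empty or
#' missing docking score is treated as the no-pose sentinel 0 with a
#' warning. When `fp_path` is given the fingerprints are read with
#' [read_fingerprints()] and joined on `id`; an id without a fingerprint
#' is an error naming the id.
#'
#' @param path dataset CSV path
#' @param fp_path optional fingerprint file path
#' @return an `ar_dataset` list with `data` and (possibly `NULL`)
#'   `fingerprints`
#' @export
read_dataset <- function(path, fp_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  data <- validate_dataset(data)
  fp <- NULL
  if (!is.null(fp_path)) {
    fp <- read_fingerprints(fp_path)
    missing_fp <- setdiff(data$id, rownames(fp))
    if (length(missing_fp)) {
      stop("id(s) present in dataset but absent from fingerprint file: ",
           paste(utils::head(missing_fp, 5L), collapse = ", "), call. = FALSE)
    }
    fp <- fp[data$id, , drop = FALSE]
  }
  structure(list(data = data, fingerprints = fp, config = NULL),
            class = "ar_dataset")
}

#' @rdname read_dataset
#' @param x an `ar_dataset` (or a list with `data` and `fingerprints`)
#' @param fp_format `"bit"` or `"hex"`, see [write_fingerprints()]
#' @export
write_dataset <- function(x, path, fp_path = NULL, fp_format = "bit") {
  utils::write.csv(x$data, path, row.names = FALSE)
  if (!is.null(fp_path)) {
    if (is.null(x$fingerprints)) stop("dataset has no fingerprints", call. = FALSE)
    write_fingerprints(x$fingerprints, fp_path, format = fp_format)
  }
  invisible(path)
}

#' Read and write fingerprint files
#'
#' Two dialects are supported, detected from the content. The primary
#' text format has one record per line, `id,bitstring`, the bitstring
#' being '0'/'1' characters of fixed length. The alternative CSV dialect
#' stores a hex-encoded column (`id,hex`), each hex digit packing four
#' bits most-significant first; fingerprint lengths must be multiples of
#' four for hex output. An optional header line `id,fingerprint` (or any
#' first line whose second field is neither binary nor hex) is skipped.
#'
#' @param path file path
#' @return integer 0/1 matrix with ids as row names
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty fingerprint file: ", path, call. = FALSE)
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed fingerprint record at line %d of %s", bad[1L], path),
         call. = FALSE)
  }
  field <- vapply(parts, `[`, "", 2L)
  is_bits <- grepl("^[01]+$", field)
  is_hex <- grepl("^[0-9a-fA-F]+$", field)
  start <- 1L
  if (!is_bits[1L] && !is_hex[1L]) start <- 2L   # header line
  if (start > length(parts)) stop("no fingerprint records in ", path, call. = FALSE)
  idx <- start:length(parts)
  use_bits <- all(is_bits[idx])
  if (!use_bits && !all(is_hex[idx])) {
    bad <- idx[!(is_bits[idx] | is_hex[idx])][1L]
    stop(sprintf("malformed fingerprint at line %d of %s", bad, path),
         call. = FALSE)
  }
  decode <- if (use_bits) decode_bits else decode_hex
  rows <- lapply(field[idx], decode)
  len <- lengths(rows)
  if (length(unique(len)) != 1L) {
    stop(sprintf("inconsistent fingerprint lengths in %s (line %d)",
                 path, idx[which(len != len[1L])[1L]]), call. = FALSE)
  }
  ids <- vapply(parts[idx], `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in fingerprint file: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  as_fingerprint_matrix(m)
}

decode_bits <- function(s) as.integer(strsplit(s, "", fixed = TRUE)[[1L]])

decode_hex <- function(s) {
  nib <- strtoi(strsplit(tolower(s), "", fixed = TRUE)[[1L]], base = 16L)
  # column j of the vapply result holds the 4 bits (MSB first) of nibble j;
  # column-major flattening restores the original bit order
  as.integer(vapply(nib, function(v) as.integer(bitwAnd(bitwShiftR(v, 3:0), 1L)),
                    integer(4L)))
}

#' @rdname read_fingerprints
#' @param fp fingerprint matrix with row names
#' @param format `"bit"` (default) or `"hex"`
#' @export
write_fingerprints <- function(fp, path, format = c("bit", "hex")) {
  format <- match.arg(format)
  fp <- as_fingerprint_matrix(fp)
  if (is.null(rownames(fp))) stop("fingerprints need row-name ids", call. = FALSE)
  enc <- if (format == "bit") {
    apply(fp, 1L, paste, collapse = "")
  } else {
    if (ncol(fp) %% 4L != 0L) {
      stop("hex output needs a fingerprint length divisible by 4", call. = FALSE)
    }
    apply(fp, 1L, function(row) {
      nib <- colSums(matrix(row, nrow = 4L) * c(8L, 4L, 2L, 1L))
      paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
              "a", "b", "c", "d", "e", "f")[nib + 1L], collapse = "")
    })
  }
  writeLines(paste0(rownames(fp), ",", enc), path)
  invisible(path)
}

#' Serialise fitted models to JSON
#'
#' Flat JSON records for the two model types: logistic models
#' (`feature_names`, `beta`, `alphas`, `ll`, `meta`) and Gaussian class
#' models (the six fitted fields). Values round-trip exactly at double
#' precision.
#'
#' @param model a `logit_ml` or `gaussian_classes` object
#' @param path output path
#' @param meta optional named list stored alongside the model
#' @export
write_model <- function(model, path, meta = NULL) {
  rec <- if (inherits(model, "logit_ml")) {
    list(type = "logistic",
         feature_names = model$feature_names,
         beta = model$beta,
         alphas = as.list(model$alphas),
         ll = model$ll,
         converged = model$converged,
         n_iter = model$n_iter,
         meta = meta)
  } else if (inherits(model, "gaussian_classes")) {
    list(type = "gaussian_classes",
         mu_act = model$mu_act, sigma_act = model$sigma_act,
         mu_inact = model$mu_inact, sigma_inact = model$sigma_inact,
         n_act = model$n_act, n_inact = model$n_inact,
         zeros_excluded = model$zeros_excluded,
         meta = meta)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(rec$type, "logistic")) {
    alphas <- vapply(rec$alphas, as.numeric, 0)
    structure(
      list(beta = as.numeric(rec$beta),
           alphas = stats::setNames(alphas, names(rec$alphas)),
           feature_names = vapply(rec$feature_names, as.character, ""),
           ll = if (is.null(rec$ll)) NA_real_ else as.numeric(rec$ll),
           converged = isTRUE(rec$converged),
           n_iter = if (is.null(rec$n_iter)) NA_integer_ else as.integer(rec$n_iter),
           separation = FALSE,
           meta = rec$meta),
      class = "logit_ml")
  } else if (identical(rec$type, "gaussian_classes")) {
    structure(
      list(mu_act = as.numeric(rec$mu_act), sigma_act = as.numeric(rec$sigma_act),
           mu_inact = as.numeric(rec$mu_inact),
           sigma_inact = as.numeric(rec$sigma_inact),
           n_act = as.integer(rec$n_act), n_inact = as.integer(rec$n_inact),
           zeros_excluded = isTRUE(rec$zeros_excluded)),
      class = "gaussian_classes")
  } else {
    stop("unrecognised model file: ", path, call. = FALSE)
  }
}

# One manifest per CLI run: command, argument snapshot, seed, package
# version, md5 digest of every input file, timestamp.
write_manifest <- function(out, command, argv, seed = NULL, inputs = character()) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(unlist(inputs, use.names = FALSE)))
  } else NULL
  rec <- list(command = command,
              arguments = as.list(argv),
              seed = seed,
              package = "arbind",
              version = as.character(utils::packageVersion("arbind")),
              inputs = digests,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- paste0(out, ".manifest.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}
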