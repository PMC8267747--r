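#' Binary molecular fingerprints
#'
#' Fingerprints are fixed-length bitstrings (0/1 vectors). A set of
#' fingerprints is stored as an integer matrix with one row per compound
#' (values 0/1) and compound identifiers as row names; all rows share the
#' same length. These are the only primitives the similarity calculus
#' needs: equality of length and popcounts of bits and bit intersections.
#'
#' @param x a vector coercible to 0/1, or a matrix of such rows
#' @return `as_fingerprint()` returns an integer 0/1 vector;
#'   `as_fingerprint_matrix()` an integer 0/1 matrix.
#' @examples
#' as_fingerprint(c(1, 0, 0, 1))
#' @export
as_fingerprint <- function(x) {
  x <- as.integer(x)
  if (length(x) == 0L || anyNA(x) || any(x != 0L & x != 1L)) {
    stop("a fingerprint must be a non-empty vector of 0/1 bits", call. = FALSE)
  }
  x
}

#' @rdname as_fingerprint
#' @export
as_fingerprint_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (nrow(x) == 0L || ncol(x) == 0L || anyNA(x) || any(x != 0L & x != 1L)) {
    stop("fingerprint matrix must be non-empty 0/1", call. = FALSE)
  }
  x
}

check_fp_pair <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("fingerprint length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
}

#' Tanimoto (Jaccard) similarity and distance between fingerprints
#'
#' For binary fingerprints A and B with popcounts N_A and N_B and
#' intersection popcount N_AB, the Tanimoto coefficient is
#' \deqn{T(A,B) = N_{AB} / (N_A + N_B - N_{AB})}
#' and the Tanimoto (Jaccard) distance is \eqn{D(A,B) = 1 - T(A,B)}.
#' The distance is a metric on bitstrings (it satisfies the triangle
#' inequality), which is what makes class-averaged distances meaningful
#' similarity features.
#'
#' Two all-zero fingerprints carry no substructure information; their
#' similarity is defined as 1 (identical emptiness) and a warning is
#' emitted, since no finite bit pattern distinguishes them.
#'
#' @param a,b fingerprints of equal length (0/1 vectors)
#' @return `tanimoto()`: similarity in \[0, 1\]; `fp_distance()`: distance
#'   in \[0, 1\].
#' @examples
#' a <- as_fingerprint(c(1, 1, 1, 0, 0))
#' b <- as_fingerprint(c(0, 1, 1, 1, 0))
#' tanimoto(a, b)     # 2 common bits, 4 in the union -> 0.5
#' fp_distance(a, b)  # 0.5
#' @export
tanimoto <- function(a, b) {
  a <- as_fingerprint(a)
  b <- as_fingerprint(b)
  check_fp_pair(a, b)
  n_ab <- sum(a & b)
  denom <- sum(a) + sum(b) - n_ab
  if (denom == 0L) {
    warning("both fingerprints are all-zero; returning similarity 1 by convention",
            call. = FALSE)
    return(1)
  }
  n_ab / denom
}

#' @rdname tanimoto
#' @export
fp_distance <- function(a, b) 1 - tanimoto(a, b)

#' Pairwise Tanimoto similarities between two fingerprint panels
#'
#' Computes the full similarity matrix between the rows of `x` and the rows
#' of `y` using popcount algebra (one cross-product of the 0/1 matrices),
#' which is what makes panel-averaged distances on thousands of compounds
#' cheap. All-zero versus all-zero pairs take similarity 1 by the same
#' convention as [tanimoto()].
#'
#' @param x fingerprint matrix (rows are compounds)
#' @param y fingerprint matrix with the same number of columns; defaults to `x`
#' @return numeric matrix of dim `nrow(x)` x `nrow(y)`
#' @export
tanimoto_matrix <- function(x, y = NULL) {
  x <- as_fingerprint_matrix(x)
  y <- if (is.null(y)) x else as_fingerprint_matrix(y)
  if (ncol(x) != ncol(y)) {
    stop(sprintf("fingerprint length mismatch: %d vs %d", ncol(x), ncol(y)),
         call. = FALSE)
  }
  common <- tcrossprod(x, y)                 # N_A&B
  nx <- rowSums(x)
  ny <- rowSums(y)
  denom <- outer(nx, ny, "+") - common       # N_A + N_B - N_A&B
  sim <- common / denom
  sim[denom == 0] <- 1                       # both all-zero
  dimnames(sim) <- list(rownames(x), rownames(y))
  sim
}

#' Average Tanimoto distance from a query to a reference panel
#'
#' The mean Tanimoto distance from one compound to every member of a
#' reference panel (e.g. the known binders, or the known non-binders).
#' When the query is itself a panel member — as happens when scoring the
#' training set — its own row must be excluded (`exclude`), otherwise the
#' average distance to its own class is biased low by the zero
#' self-distance.
#'
#' @param query a single fingerprint (0/1 vector)
#' @param panel fingerprint matrix, one reference compound per row
#' @param exclude optional row index of `query` within `panel` to leave out
#' @return mean distance in \[0, 1\]
#' @examples
#' panel <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0))
#' avg_fp_distance(c(1, 1, 0, 0), panel)             # (0 + 2/3) / 2
#' avg_fp_distance(c(1, 1, 0, 0), panel, exclude = 1) # 2/3
#' @export
avg_fp_distance <- function(query, panel, exclude = NULL) {
  query <- as_fingerprint(query)
  panel <- as_fingerprint_matrix(panel)
  if (!is.null(exclude)) {
    if (length(exclude) != 1L || exclude < 1L || exclude > nrow(panel)) {
      stop("'exclude' must be a single valid panel row index", call. = FALSE)
    }
    panel <- panel[-exclude, , drop = FALSE]
  }
  if (nrow(panel) == 0L) {
    stop("reference panel is empty after exclusion", call. = FALSE)
  }
  sims <- tanimoto_matrix(matrix(query, nrow = 1L), panel)
  mean(1 - sims)
}

#' Extended-connectivity fingerprints from SMILES (optional adapter)
#'
#' Computes Morgan/ECFP bit fingerprints for a vector of SMILES strings by
#' delegating to an RDKit installation reachable through the `python`
#' executable on the PATH. This is an optional convenience adapter: the
#' rest of the package consumes precomputed bitstrings and never requires
#' it. Radius 2 with 1024 bits (the common ECFP4 setting) is the default.
#'
#' @param smiles character vector of SMILES strings
#' @param radius Morgan radius (2 corresponds to ECFP4)
#' @param nbits fingerprint length in bits
#' @param python path to the python executable used to reach RDKit
#' @return fingerprint matrix with `length(smiles)` rows, rownames taken
#'   from `names(smiles)` when present
#' @export
smiles_to_ecfp <- function(smiles, radius = 2L, nbits = 1024L,
                           python = Sys.which("python")) {
  if (!is.character(smiles) || length(smiles) == 0L) {
    stop("'smiles' must be a non-empty character vector", call. = FALSE)
  }
  if (!nzchar(python) || !file.exists(python)) {
    stop("smiles_to_ecfp() needs the optional RDKit toolkit: no usable ",
         "'python' executable was found", call. = FALSE)
  }
  script <- sprintf(
    "import sys\ntry:\n    from rdkit import Chem\n    from rdkit.Chem import rdFingerprintGenerator\nexcept ImportError:\n    sys.stderr.write('NO_RDKIT')\n    sys.exit(3)\ngen = rdFingerprintGenerator.GetMorganGenerator(radius=%d, fpSize=%d)\nfor line in sys.stdin:\n    smi = line.strip()\n    mol = Chem.MolFromSmiles(smi)\n    if mol is None:\n        sys.stderr.write('BAD_SMILES:' + smi)\n        sys.exit(4)\n    print(gen.GetFingerprint(mol).ToBitString())\n",
    as.integer(radius), as.integer(nbits))
  out <- suppressWarnings(system2(python, c("-c", shQuote(script)),
                                  input = smiles,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    if (any(grepl("NO_RDKIT", out))) {
      stop("smiles_to_ecfp() needs the optional RDKit toolkit, which is not ",
           "importable from ", python, call. = FALSE)
    }
    bad <- sub("^BAD_SMILES:", "", grep("^BAD_SMILES:", out, value = TRUE))
    if (length(bad)) {
      stop("unparsable SMILES: ", bad[1L], call. = FALSE)
    }
    stop("fingerprint generation failed: ", paste(out, collapse = " "),
         call. = FALSE)
  }
  bits <- do.call(rbind, lapply(out, function(s) {
    as.integer(strsplit(s, "", fixed = TRUE)[[1L]])
  }))
  rownames(bits) <- names(smiles)
  as_fingerprint_matrix(bits)
}
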