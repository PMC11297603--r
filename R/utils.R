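#' Pack a binary fingerprint into a hex string (and back)
#'
#' Compact text encoding for fingerprint columns in CSV files: bits are
#' taken in groups of four, most significant first, and written as hex
#' digits. The bit length must be a multiple of 4.
#'
#' @param bits 0/1 vector, or a matrix (one row per chemical).
#' @return hex string(s).
#' @export
#' @examples
#' bitsToHex(c(1, 0, 1, 0, 1, 1, 1, 1))  # "af"
bitsToHex <- function(bits) {
  if (is.matrix(bits))
    return(apply(bits, 1L, bitsToHex))
  n <- length(bits)
  if (n %% 4L != 0L) stop("bit length must be a multiple of 4")
  m <- matrix(as.integer(bits), nrow = 4L)
  vals <- as.integer(c(8L, 4L, 2L, 1L) %*% m)
  paste(substring("0123456789abcdef", vals + 1L, vals + 1L), collapse = "")
}

#' @rdname bitsToHex
#' @param hex hex string(s) as produced by \code{bitsToHex}.
#' @param asMatrix return a matrix for vector input.
#' @export
hexToBits <- function(hex, asMatrix = length(hex) > 1L) {
  one <- function(h) {
    digits <- strtoi(strsplit(tolower(h), "")[[1]], base = 16L)
    if (anyNA(digits)) stop("not a hex string: ", h)
    as.integer(rbind(digits %/% 8L %% 2L, digits %/% 4L %% 2L,
                     digits %/% 2L %% 2L, digits %% 2L))
  }
  if (length(hex) == 1L && !asMatrix) return(one(hex))
  t(vapply(hex, one, integer(4L * nchar(hex[1]))))
}

# Write one task dataset as CSV (chem_id, fp_hex, label[, split]).
writeTaskCSV <- function(task, path) {
  df <- data.frame(chem_id = task@chemIds,
                   fp_hex = bitsToHex(task@X),
                   label = task@y,
                   split = task@split,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Read a task CSV written by writeTaskCSV.
readTaskCSV <- function(path, taskName, group = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chem_id = "character",
                                       fp_hex = "character"))
  X <- hexToBits(df$fp_hex, asMatrix = TRUE)
  colnames(X) <- paste0("F", seq_len(ncol(X)))
  split <- if ("split" %in% names(df)) df$split else rep("unsplit", nrow(df))
  taskDataset(taskName, df$chem_id, X, df$label, split = split, group = group)
}
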