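#' Parse a crisp-set Boolean expression into an implicant matrix
#'
#' Expressions follow the csQCA notation: `*` is logical AND, `+` is logical
#' OR, and negation is written by lower-casing a condition name, so
#' `"FMC*ecg*TWT"` means FMC delayed AND ECG not delayed AND TWT delayed.
#' The token `TRUE` denotes the tautology (always satisfied).
#'
#' @param expr Expression string.
#' @param conditions Ordered character vector of condition names (upper case
#'   is the canonical spelling).
#' @return Integer matrix with one row per implicant and one column per
#'   condition; entries are 1 (present), 0 (absent) or NA (free).
#' @examples
#' parse_qca_expression("ecg*txf*TWT + FMC*ecg*TWT", c("FMC", "ECG", "TXF", "TWT"))
#' @export
parse_qca_expression <- function(expr, conditions = stemi_stages) {
  stopifnot(is.character(expr), length(expr) == 1)
  terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) {
    rlang::abort("empty expression")
  }
  rows <- lapply(terms, function(term) {
    row <- rep(NA_integer_, length(conditions))
    if (identical(toupper(term), "TRUE")) {
      return(row)
    }
    lits <- trimws(strsplit(term, "*", fixed = TRUE)[[1]])
    for (lit in lits) {
      idx <- match(toupper(lit), toupper(conditions))
      if (is.na(idx)) {
        rlang::abort(paste0(
          "unknown condition '", lit, "' in expression (known: ",
          paste(conditions, collapse = ", "), ")"
        ))
      }
      value <- if (identical(lit, toupper(lit))) 1L else 0L
      if (!is.na(row[idx]) && row[idx] != value) {
        rlang::abort(paste0("contradictory literals for '", conditions[idx],
                            "' within one term"))
      }
      row[idx] <- value
    }
    row
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- conditions
  mat
}

#' Format an implicant matrix as a canonical csQCA expression string
#'
#' Literals appear in declared condition order, upper case for presence and
#' lower case for absence; implicants are joined by `" + "` and sorted
#' canonically (per condition: free before absent before present). The
#' tautology implicant formats as `"TRUE"`.
#'
#' @param implicants Integer matrix as produced by [parse_qca_expression()].
#' @param conditions Ordered condition names; defaults to the matrix
#'   column names.
#' @return A single string; `parse_qca_expression()` of the result recovers
#'   the implicant matrix.
#' @export
format_qca_expression <- function(implicants, conditions = colnames(implicants)) {
  stopifnot(is.matrix(implicants), ncol(implicants) == length(conditions))
  if (nrow(implicants) == 0) rlang::abort("no implicants to format")
  ord <- order_implicants(implicants)
  implicants <- implicants[ord, , drop = FALSE]
  terms <- apply(implicants, 1, function(row) {
    lits <- character(0)
    for (j in seq_along(conditions)) {
      if (is.na(row[j])) next
      lits <- c(lits, if (row[j] == 1) toupper(conditions[j]) else tolower(conditions[j]))
    }
    if (length(lits) == 0) "TRUE" else paste(lits, collapse = "*")
  })
  paste(unique(terms), collapse = " + ")
}

# Canonical implicant order: compare position by position in declared
# condition order with free (NA) < absent (0) < present (1).
order_implicants <- function(implicants) {
  keys <- apply(implicants, 2, function(col) {
    k <- ifelse(is.na(col), 0L, col + 1L)
    k
  })
  if (is.null(dim(keys))) keys <- matrix(keys, nrow = nrow(implicants))
  do.call(order, as.data.frame(keys))
}

#' Evaluate a Boolean expression on a matrix of binary conditions
#'
#' @param expr Expression string or implicant matrix.
#' @param data Data frame (or matrix) with one 0/1 column per condition.
#' @param conditions Ordered condition names.
#' @return Integer 0/1 vector, one entry per row of `data`.
#' @examples
#' flags <- data.frame(FMC = 1, ECG = 0, TXF = 0, TWT = 1)
#' eval_qca_expression("ecg*txf*TWT + FMC*ecg*TWT", flags)
#' @export
eval_qca_expression <- function(expr, data, conditions = stemi_stages) {
  implicants <- if (is.matrix(expr)) expr else parse_qca_expression(expr, conditions)
  conditions <- colnames(implicants)
  missing <- setdiff(conditions[apply(!is.na(implicants), 2, any)], names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("data missing condition column(s): ",
                        paste(missing, collapse = ", ")))
  }
  n <- nrow(data)
  out <- rep(FALSE, n)
  for (i in seq_len(nrow(implicants))) {
    hit <- rep(TRUE, n)
    for (j in seq_along(conditions)) {
      v <- implicants[i, j]
      if (is.na(v)) next
      hit <- hit & (data[[conditions[j]]] == v)
    }
    out <- out | hit
  }
  as.integer(out)
}
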