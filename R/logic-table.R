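#' Boolean logic table
#'
#' A logic table gives the next state of a target node for every combination
#' of its regulator states.  Rows are indexed by reading the input tuple as a
#' binary number with the first listed input as the most significant bit, so
#' a table over inputs `(A, C)` stores its outputs in the row order
#' `A=0,C=0`, `A=0,C=1`, `A=1,C=0`, `A=1,C=1`.
#'
#' @param target Node id the table drives.
#' @param inputs Character vector of regulator node ids (ordered, distinct).
#'   May be empty, in which case the node is a constant.
#' @param outputs Integer vector of 0/1 of length `2^length(inputs)`.
#' @return An object of class `logic_table`.
#' @examples
#' logic_table("B", c("A", "C"), c(0, 1, 1, 1)) # B <- A OR C
#' @export
logic_table <- function(target, inputs, outputs) {
  stopifnot(is.character(target), length(target) == 1L, nzchar(target))
  inputs <- as.character(inputs)
  if (anyDuplicated(inputs)) {
    stop("duplicate input for node '", target, "'", call. = FALSE)
  }
  outputs <- as.integer(outputs)
  if (length(outputs) != 2L^length(inputs)) {
    stop("table for node '", target, "' has ", length(outputs),
         " outputs; expected 2^", length(inputs), call. = FALSE)
  }
  if (anyNA(outputs) || !all(outputs %in% c(0L, 1L))) {
    stop("non-binary output in table for node '", target, "'", call. = FALSE)
  }
  structure(list(target = target, inputs = inputs, outputs = outputs),
            class = "logic_table")
}

#' @export
print.logic_table <- function(x, ...) {
  k <- length(x$inputs)
  cat("<logic_table> ", x$target, " <- f(",
      paste(x$inputs, collapse = ", "), ")\n", sep = "")
  if (k == 0L) {
    cat("  constant ", x$outputs, "\n", sep = "")
  } else {
    rows <- t(vapply(seq_along(x$outputs) - 1L, int_to_bits,
                     integer(k), k = k))
    for (i in seq_along(x$outputs)) {
      cat(" ", paste(rows[i, ], collapse = " "), "->", x$outputs[i], "\n")
    }
  }
  invisible(x)
}

#' Fix one input of a logic table at a value
#'
#' Projects a `k`-input table to the `k - 1`-input table obtained when one
#' regulator is held at a constant value; the relative order of the remaining
#' inputs is preserved.  This is the reduced table used both to test whether
#' an edge is insignificant and to delete an edge from a network.
#'
#' @param table A [logic_table()].
#' @param input Id of the input to fix; must occur in `table$inputs`.
#' @param value 0 or 1.
#' @return A [logic_table()] over the remaining inputs.
#' @examples
#' tb <- logic_table("B", c("A", "C"), c(0, 1, 1, 1))
#' reduced_table(tb, "A", 0) # B <- C
#' @export
reduced_table <- function(table, input, value) {
  stopifnot(inherits(table, "logic_table"))
  pos <- match(input, table$inputs)
  if (is.na(pos)) {
    stop("'", input, "' is not an input of node '", table$target, "'",
         call. = FALSE)
  }
  value <- as.integer(value)
  stopifnot(value %in% c(0L, 1L))
  k <- length(table$inputs)
  rows <- seq_len(2L^k) - 1L
  keep <- bitwAnd(rows %/% 2L^(k - pos), 1L) == value
  logic_table(table$target, table$inputs[-pos], table$outputs[keep])
}

# Output vector of a table evaluated at a named binary assignment of its
# inputs (assignment may contain extra nodes).
eval_table <- function(table, assignment) {
  k <- length(table$inputs)
  if (k == 0L) return(table$outputs[1L])
  row <- sum(assignment[table$inputs] * bit_weights(k))
  table$outputs[row + 1L]
}
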