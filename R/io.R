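#' Read and write Boolean network models
#'
#' Two plain-text dialects are supported.
#'
#' **`truthtable_csv`**: one block per regulated node.  A block starts with a
#' header line `node,<input ids>` and is followed by `2^k` rows
#' `bit,...,bit,output`, with the input tuple read as a binary number (first
#' input = most significant bit).  Lines starting with `#` are comments; the
#' pragma `#!inputs A=0,B=1` optionally declares input nodes and their clamp
#' values (inputs referenced by tables but never declared are detected
#' automatically and clamped to 0).
#'
#' **`expr`**: one line per regulated node, `target = <expression>` with
#' operators `AND`/`OR`/`NOT` (equivalently `&`, `|`, `!`), parentheses and
#' the constants `0` and `1`.  Tables are compiled by exhaustive evaluation
#' over the regulators, in order of first appearance in the expression.  The
#' same `#!inputs` pragma is honored.
#'
#' `parse_network()` accepts a character vector of lines (or one string with
#' embedded newlines); `read_network()` reads a file.  `write_network()` is
#' the exact inverse of `parse_network()`: the node set, edge set, clamp
#' values and all truth-table outputs round-trip bit-exactly.
#'
#' @param text Character vector with the model text.
#' @param format `"truthtable_csv"` or `"expr"`.
#' @return `parse_network()`/`read_network()`: a [boolean_network()].
#'   `write_network()`: a character vector of lines.
#' @examples
#' net <- parse_network(c("B = A | C", "C = B"))
#' network_edges(net)
#' identical_lines <- write_network(net, "expr")
#' @export
parse_network <- function(text, format = c("truthtable_csv", "expr")) {
  format <- match.arg(format)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  pragma <- parse_inputs_pragma(lines)
  body <- lines[!grepl("^\\s*#", lines)]
  tables <- switch(format,
    truthtable_csv = parse_truthtable_csv(body),
    expr = parse_expr_dialect(body)
  )
  targets <- vapply(tables, function(tb) tb$target, character(1))
  declared <- names(pragma)
  if (length(bad <- intersect(declared, targets))) {
    stop("format error: node '", bad[1L],
         "' declared as input but has a table", call. = FALSE)
  }
  boolean_network(tables, inputs = declared,
                  clamp = if (length(pragma)) pragma else NULL)
}

#' @rdname parse_network
#' @param path File path.
#' @export
read_network <- function(path, format = c("truthtable_csv", "expr")) {
  parse_network(readLines(path, warn = FALSE), match.arg(format))
}

#' @rdname parse_network
#' @param net A [boolean_network()].
#' @export
write_network <- function(net, format = c("truthtable_csv", "expr")) {
  stopifnot(inherits(net, "boolean_network"))
  format <- match.arg(format)
  out <- character()
  if (length(net$inputs)) {
    out <- paste0("#!inputs ",
                  paste0(net$inputs, "=", net$clamp[net$inputs],
                         collapse = ","))
  }
  body <- switch(format,
    truthtable_csv = unlist(lapply(net$tables, format_table_csv)),
    expr = vapply(net$tables, format_table_expr, character(1))
  )
  c(out, unname(body))
}

#' @rdname parse_network
#' @export
write_network_file <- function(net, path,
                               format = c("truthtable_csv", "expr")) {
  writeLines(write_network(net, match.arg(format)), path)
  invisible(path)
}

parse_inputs_pragma <- function(lines) {
  hits <- grep("^\\s*#!inputs\\b", lines, value = TRUE)
  clamp <- integer(0)
  for (h in hits) {
    spec <- sub("^\\s*#!inputs\\s*", "", h)
    parts <- trimws(unlist(strsplit(spec, "[,;[:space:]]+")))
    parts <- parts[nzchar(parts)]
    for (p in parts) {
      kv <- strsplit(p, "=", fixed = TRUE)[[1L]]
      val <- if (length(kv) == 2L) as.integer(kv[2L]) else 0L
      if (is.na(val) || !val %in% c(0L, 1L)) {
        stop("format error in inputs pragma: '", p, "'", call. = FALSE)
      }
      clamp[kv[1L]] <- val
    }
  }
  clamp
}

# --- truth-table CSV --------------------------------------------------------

parse_truthtable_csv <- function(lines) {
  tables <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    header <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1L]])
    node <- header[1L]
    ins <- header[-1L][nzchar(header[-1L])]
    if (!nzchar(node)) {
      stop("format error at line ", i, ": empty node id", call. = FALSE)
    }
    if (node %in% names(tables)) {
      stop("format error at line ", i, ": duplicate node '", node, "'",
           call. = FALSE)
    }
    k <- length(ins)
    rows <- 2L^k
    outputs <- integer(rows)
    seen <- logical(rows)
    for (r in seq_len(rows)) {
      j <- i + r
      if (j > n || !nzchar(trimws(lines[j]))) {
        stop("format error at line ", i, ": table for '", node, "' has ",
             r - 1L, " rows; expected ", rows, call. = FALSE)
      }
      cells <- trimws(strsplit(lines[j], ",", fixed = TRUE)[[1L]])
      if (length(cells) != k + 1L) {
        stop("format error at line ", j, ": expected ", k + 1L,
             " comma-separated values", call. = FALSE)
      }
      vals <- suppressWarnings(as.integer(cells))
      if (anyNA(vals) || !all(vals %in% c(0L, 1L))) {
        stop("format error at line ", j, ": non-binary symbol", call. = FALSE)
      }
      row_idx <- if (k == 0L) 0L else sum(vals[seq_len(k)] * bit_weights(k))
      if (seen[row_idx + 1L]) {
        stop("format error at line ", j, ": duplicate row for '", node, "'",
             call. = FALSE)
      }
      seen[row_idx + 1L] <- TRUE
      outputs[row_idx + 1L] <- vals[k + 1L]
    }
    nxt <- i + rows + 1L
    if (nxt <= n && nzchar(trimws(lines[nxt])) &&
        length(strsplit(lines[nxt], ",", fixed = TRUE)[[1L]]) == k + 1L &&
        !anyNA(suppressWarnings(
          as.integer(strsplit(lines[nxt], ",", fixed = TRUE)[[1L]])))) {
      stop("format error at line ", nxt, ": table for '", node,
           "' has more than ", rows, " rows", call. = FALSE)
    }
    tables[[node]] <- logic_table(node, ins, outputs)
    i <- i + rows + 1L
  }
  unname(tables)
}

format_table_csv <- function(tb) {
  k <- length(tb$inputs)
  header <- paste(c(tb$target, tb$inputs), collapse = ",")
  rows <- vapply(seq_along(tb$outputs) - 1L, function(r) {
    paste(c(int_to_bits(r, k), tb$outputs[r + 1L]), collapse = ",")
  }, character(1))
  c(header, rows, "")
}

# --- expression dialect -----------------------------------------------------

expr_tokenize <- function(s, line) {
  tokens <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", "&", "|", "!")) {
      type <- switch(ch, "(" = "LP", ")" = "RP", "&" = "AND",
                     "|" = "OR", "!" = "NOT")
      tokens[[length(tokens) + 1L]] <- list(type = type)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(s, i, n),
                    regexpr("^[^()&|![:space:]]+", substr(s, i, n)))
    if (length(m) == 0L) {
      stop("format error at line ", line, ": unexpected character '", ch, "'",
           call. = FALSE)
    }
    word <- m[[1L]]
    type <- switch(toupper(word), AND = "AND", OR = "OR", NOT = "NOT", NULL)
    tokens[[length(tokens) + 1L]] <-
      if (!is.null(type)) list(type = type) else list(type = "ID", id = word)
    i <- i + nchar(word)
  }
  tokens
}

# Recursive-descent parser; precedence NOT > AND > OR.  Returns an AST of
# nested lists plus the regulators in order of first appearance.
expr_parse <- function(tokens, line) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]]$type else "END"
  take <- function() { tk <- tokens[[pos]]; pos <<- pos + 1L; tk }
  parse_or <- function() {
    node <- parse_and()
    while (peek() == "OR") { take(); node <- list(op = "or", a = node, b = parse_and()) }
    node
  }
  parse_and <- function() {
    node <- parse_not()
    while (peek() == "AND") { take(); node <- list(op = "and", a = node, b = parse_not()) }
    node
  }
  parse_not <- function() {
    if (peek() == "NOT") { take(); return(list(op = "not", a = parse_not())) }
    if (peek() == "LP") {
      take()
      node <- parse_or()
      if (peek() != "RP") stop("format error at line ", line,
                               ": missing ')'", call. = FALSE)
      take()
      return(node)
    }
    if (peek() == "ID") {
      tk <- take()
      if (tk$id %in% c("0", "1")) {
        return(list(op = "const", value = as.integer(tk$id)))
      }
      return(list(op = "var", id = tk$id))
    }
    stop("format error at line ", line, ": unexpected token", call. = FALSE)
  }
  ast <- parse_or()
  if (peek() != "END") {
    stop("format error at line ", line, ": trailing tokens", call. = FALSE)
  }
  ast
}

ast_vars <- function(ast) {
  switch(ast$op,
    var = ast$id,
    const = character(0),
    not = ast_vars(ast$a),
    unique(c(ast_vars(ast$a), ast_vars(ast$b)))
  )
}

ast_eval <- function(ast, env) {
  switch(ast$op,
    var = env[[ast$id]],
    const = ast$value,
    not = 1L - ast_eval(ast$a, env),
    and = ast_eval(ast$a, env) * ast_eval(ast$b, env),
    or = as.integer(ast_eval(ast$a, env) + ast_eval(ast$b, env) > 0L)
  )
}

parse_expr_dialect <- function(lines) {
  tables <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0L) {
      stop("format error at line ", i, ": expected 'target = expression'",
           call. = FALSE)
    }
    target <- trimws(substr(ln, 1L, eq - 1L))
    if (!nzchar(target) || grepl("[()&|![:space:]]", target)) {
      stop("format error at line ", i, ": bad target id", call. = FALSE)
    }
    if (target %in% names(tables)) {
      stop("format error at line ", i, ": duplicate node '", target, "'",
           call. = FALSE)
    }
    ast <- expr_parse(expr_tokenize(substr(ln, eq + 1L, nchar(ln)), i), i)
    ins <- ast_vars(ast)
    k <- length(ins)
    outputs <- vapply(seq_len(2L^k) - 1L, function(r) {
      bits <- int_to_bits(r, k)
      ast_eval(ast, as.list(setNames(as.list(bits), ins)))
    }, integer(1))
    tables[[target]] <- logic_table(target, ins, outputs)
  }
  unname(tables)
}

# Sum-of-products rendering of a table; exact inverse under re-compilation.
format_table_expr <- function(tb) {
  k <- length(tb$inputs)
  on_rows <- which(tb$outputs == 1L) - 1L
  rhs <- if (length(on_rows) == 0L && k > 0L) {
    # keep the regulators in the text so the edge set round-trips
    paste0("(", paste(tb$inputs, collapse = " | "), ") & 0")
  } else if (length(on_rows) == 0L) {
    "0"
  } else if (length(on_rows) == 2L^k && k > 0L) {
    # keep the regulators in the text so the edge set round-trips
    paste0("(", paste(tb$inputs, collapse = " | "), ") | 1")
  } else if (k == 0L) {
    as.character(tb$outputs[1L])
  } else {
    terms <- vapply(on_rows, function(r) {
      bits <- int_to_bits(r, k)
      lits <- ifelse(bits == 1L, tb$inputs, paste0("!", tb$inputs))
      paste0("(", paste(lits, collapse = " & "), ")")
    }, character(1))
    paste(terms, collapse = " | ")
  }
  paste(tb$target, "=", rhs)
}

#' Write a classified edge list
#'
#' Emits a three-column TSV `source<TAB>target<TAB>class`, with class
#' `core`, `neighbor` or `unassigned`.  Accepts either a decomposition
#' (classes taken from it) or a plain network (all edges `unassigned`).
#'
#' @param x A [decompose()] result or a [boolean_network()].
#' @param path Output file path.
#' @export
write_edge_classes <- function(x, path) {
  tbl <- if (inherits(x, "bn_decomposition")) {
    dplyr::select(tidy(x), "source", "target", class = "class")
  } else if (inherits(x, "boolean_network")) {
    dplyr::mutate(network_edges(x), class = "unassigned")
  } else {
    stop("'x' must be a boolean_network or a decomposition", call. = FALSE)
  }
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
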