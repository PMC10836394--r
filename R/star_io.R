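#' STAR document containers
#'
#' A `star_document` is an ordered list of [star_block()] objects with unique
#' names; it is the universal metadata carrier of a RELION project. A
#' `star_block` holds an ordered set of simple label/value pairs, a loop
#' table (a `data.frame`), or both. Labels are stored without the leading
#' underscore they carry in serialized form (`_rlnMicrographName` becomes
#' column `rlnMicrographName`).
#'
#' @param blocks list of `star_block` objects, unique names.
#' @return `star_document()` returns an object of class `star_document`.
#' @examples
#' doc <- star_document(list(star_block("x", pairs = list(a = 1L))))
#' names(doc$blocks)
#' @export
star_document <- function(blocks = list()) {
  nm <- vapply(blocks, function(b) b$name, character(1))
  if (anyDuplicated(nm)) {
    relmeta_stop("duplicate block name '%s' in document",
                 nm[duplicated(nm)][1], class = "relmeta_parse_error")
  }
  names(blocks) <- nm
  structure(list(blocks = blocks), class = "star_document")
}

#' @rdname star_document
#' @param name block name as serialized after the `data_` keyword
#'   (e.g. `"micrographs"` for `data_micrographs`).
#' @param pairs named list of scalars (simple `_label value` pairs).
#' @param table `data.frame` backing the `loop_` section, or `NULL`.
#' @export
star_block <- function(name, pairs = list(), table = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(pairs) && anyDuplicated(names(pairs))) {
    relmeta_stop("duplicate pair label in block '%s'", name,
                 class = "relmeta_parse_error")
  }
  if (!is.null(table)) {
    stopifnot(is.data.frame(table))
    if (anyDuplicated(names(table))) {
      relmeta_stop("duplicate loop label in block '%s'", name,
                   class = "relmeta_parse_error")
    }
    rownames(table) <- NULL
  }
  structure(list(name = name, pairs = pairs, table = table),
            class = "star_block")
}

#' @export
print.star_document <- function(x, ...) {
  cat(sprintf("<star_document: %d block(s)>\n", length(x$blocks)))
  for (b in x$blocks) {
    cat(sprintf("  data_%s: %d pair(s)%s\n", b$name, length(b$pairs),
                if (is.null(b$table)) "" else
                  sprintf(", loop %d x %d", nrow(b$table), ncol(b$table))))
  }
  invisible(x)
}

# Split one physical line into STAR tokens: whitespace-delimited, with
# single/double-quoted strings kept intact and '#' starting a comment
# (outside quotes).
tokenize_star_line <- function(line) {
  tokens <- character(0)
  i <- 1L
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == "\"") {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      tokens <- c(tokens, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[[:space:]]$", substr(line, j, j))) j <- j + 1L
      tokens <- c(tokens, substr(line, i, j - 1L))
      i <- j
    }
  }
  tokens
}

#' Parse STAR-format text
#'
#' Parses the text of a STAR file (`data_` blocks with `_label value` pairs
#' and `loop_` tables) into a [star_document()]. Comments (`#`) are
#' discarded. Columns whose cells all look like integer literals are typed
#' integer, all-real columns double, anything else is kept as text.
#'
#' @param text character: either a single string or a vector of lines.
#' @return a `star_document`.
#' @seealso [read_star()] to parse from a file, [write_star()] for the
#'   inverse operation.
#' @examples
#' doc <- parse_star("data_x\n_a 1\n")
#' doc$blocks$x$pairs$a
#' @export
parse_star <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  blocks <- list()
  cur_name <- NULL
  cur_pairs <- list()
  cur_labels <- character(0)
  cur_rows <- list()
  in_loop_header <- FALSE
  in_loop_body <- FALSE

  flush_block <- function() {
    if (is.null(cur_name)) return()
    tab <- NULL
    if (length(cur_labels)) {
      cols <- vector("list", length(cur_labels))
      if (length(cur_rows)) {
        m <- do.call(rbind, cur_rows)
        for (k in seq_along(cur_labels)) cols[[k]] <- type_tokens(m[, k])
      } else {
        for (k in seq_along(cur_labels)) cols[[k]] <- character(0)
      }
      names(cols) <- sub("^_", "", cur_labels)
      tab <- data.frame(cols, check.names = FALSE,
                        stringsAsFactors = FALSE)
    }
    if (cur_name %in% vapply(blocks, function(b) b$name, character(1))) {
      relmeta_stop("duplicate block name '%s'", cur_name,
                   class = "relmeta_parse_error")
    }
    blocks[[length(blocks) + 1L]] <<- star_block(cur_name, cur_pairs, tab)
  }

  for (ln in seq_along(lines)) {
    toks <- tokenize_star_line(lines[ln])
    if (!length(toks)) next
    first <- toks[1]
    if (grepl("^data_", first)) {
      flush_block()
      cur_name <- sub("^data_", "", first)
      cur_pairs <- list()
      cur_labels <- character(0)
      cur_rows <- list()
      in_loop_header <- FALSE
      in_loop_body <- FALSE
    } else if (first == "loop_") {
      if (is.null(cur_name)) {
        relmeta_stop("line %d: loop_ outside any data_ block", ln,
                     class = "relmeta_parse_error")
      }
      in_loop_header <- TRUE
      in_loop_body <- FALSE
    } else if (startsWith(first, "_")) {
      if (is.null(cur_name)) {
        relmeta_stop("line %d: label outside any data_ block", ln,
                     class = "relmeta_parse_error")
      }
      if (in_loop_header) {
        cur_labels <- c(cur_labels, first)
      } else {
        if (length(toks) < 2L) {
          relmeta_stop("line %d: pair '%s' has no value", ln, first,
                       class = "relmeta_parse_error")
        }
        lab <- sub("^_", "", first)
        if (lab %in% names(cur_pairs)) {
          relmeta_stop("line %d: duplicate pair label '%s'", ln, first,
                       class = "relmeta_parse_error")
        }
        val <- type_tokens(toks[2])
        cur_pairs[[lab]] <- val
        in_loop_body <- FALSE
      }
    } else {
      # data row of the current loop
      if (in_loop_header) { in_loop_header <- FALSE; in_loop_body <- TRUE }
      if (!in_loop_body || !length(cur_labels)) {
        relmeta_stop("line %d: unexpected token '%s'", ln, first,
                     class = "relmeta_parse_error")
      }
      if (length(toks) != length(cur_labels)) {
        relmeta_stop(
          "line %d: loop row has %d cell(s) but %d label(s) declared",
          ln, length(toks), length(cur_labels),
          class = "relmeta_parse_error")
      }
      cur_rows[[length(cur_rows) + 1L]] <- toks
    }
  }
  flush_block()
  star_document(blocks)
}

#' @rdname parse_star
#' @param path path to a STAR file on disk.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) {
    relmeta_stop("STAR file not found: %s", path,
                 class = "relmeta_lookup_error")
  }
  parse_star(readLines(path, warn = FALSE))
}

format_star_table <- function(table) {
  labs <- names(table)
  bad <- grepl("^_", labs)
  if (any(bad)) {
    relmeta_stop("loop label '%s' must be stored without its underscore",
                 labs[bad][1], class = "relmeta_validation_error")
  }
  out <- c("loop_", paste0("_", labs))
  if (nrow(table)) {
    cols <- lapply(table, format_scalar)
    width <- vapply(cols, function(cl) max(nchar(cl)), integer(1))
    rows <- do.call(paste, c(mapply(function(cl, w) formatC(cl, width = w),
                                    cols, width, SIMPLIFY = FALSE),
                             sep = "  "))
    out <- c(out, rows)
  }
  out
}

#' Serialize a STAR document
#'
#' Writes a [star_document()] back to STAR text. Within a block, simple
#' pairs are emitted before the loop table. Reals are rendered with six
#' decimal places (fixed notation, scientific for extreme magnitudes), so
#' round-trip equality holds after one write: `parse_star(write_star(d))`
#' equals `d` for any document already at serialization precision, and
#' writing is byte-idempotent.
#'
#' @param doc a `star_document`.
#' @param path optional output file; when `NULL` the text is returned.
#' @return the serialized text as a single string (invisibly when `path`
#'   is given).
#' @export
write_star <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "star_document"))
  out <- c("# written by relmeta", "")
  for (b in doc$blocks) {
    out <- c(out, paste0("data_", b$name), "")
    if (length(b$pairs)) {
      labs <- names(b$pairs)
      if (any(grepl("^_", labs))) {
        relmeta_stop("pair label '%s' must be stored without its underscore",
                     labs[grepl("^_", labs)][1],
                     class = "relmeta_validation_error")
      }
      vals <- vapply(b$pairs, function(v) format_scalar(v)[1], character(1))
      w <- max(nchar(labs)) + 1L
      out <- c(out, sprintf("%-*s %s", w, paste0("_", labs), vals), "")
    }
    if (!is.null(b$table)) {
      out <- c(out, format_star_table(b$table), "")
    }
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Extract a loop table from a STAR document
#'
#' @param doc a `star_document`.
#' @param block block name (with or without the `data_` prefix), or
#'   `"first-loop"` for the first block that contains a loop table. RELION
#'   files typically name blocks `data_optics`, `data_micrographs`,
#'   `data_particles`.
#' @return the block's loop table as a `data.frame`.
#' @export
get_table <- function(doc, block = "first-loop") {
  stopifnot(inherits(doc, "star_document"))
  avail <- vapply(doc$blocks, function(b) b$name, character(1))
  if (identical(block, "first-loop")) {
    for (b in doc$blocks) if (!is.null(b$table)) return(b$table)
    relmeta_stop("no block with a loop table; blocks present: %s",
                 paste0("data_", avail, collapse = ", "),
                 class = "relmeta_lookup_error")
  }
  want <- sub("^data_", "", block)
  if (!want %in% avail) {
    relmeta_stop("block 'data_%s' not found; blocks present: %s",
                 want, paste0("data_", avail, collapse = ", "),
                 class = "relmeta_lookup_error")
  }
  b <- doc$blocks[[want]]
  if (is.null(b$table)) {
    relmeta_stop("block 'data_%s' has no loop table", want,
                 class = "relmeta_lookup_error")
  }
  b$table
}

#' Append a column to a loop table
#'
#' Used to attach derived per-row metadata, e.g. the
#' `rlnMicrographIceThickness` ice score, as the table's last label.
#'
#' @param table a loop table (`data.frame`).
#' @param label new label (stored without the leading underscore).
#' @param values vector of length `nrow(table)`.
#' @return the table with the column appended.
#' @export
add_column <- function(table, label, values) {
  stopifnot(is.data.frame(table))
  label <- sub("^_", "", label)
  if (label %in% names(table)) {
    relmeta_stop("label '%s' already present in table", label,
                 class = "relmeta_validation_error")
  }
  if (length(values) != nrow(table)) {
    relmeta_stop("got %d value(s) for a table of %d row(s)",
                 length(values), nrow(table),
                 class = "relmeta_validation_error")
  }
  table[[label]] <- values
  rownames(table) <- NULL
  table
}
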