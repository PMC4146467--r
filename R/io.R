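#' Read a logical network from a directory of per-node truth-table files
#'
#' Each node is one plain-text file `<name>.txt` containing header lines
#' followed by the complete truth table, one row per line:
#'
#' ```
#' node: Ca
#' arity: 3
#' role: concentration
#' regulators: LVA HVA cAMPCC HCN CaP NCE Ca
#' 0 0 0 0 0 0 0 0
#' 0 0 0 0 0 0 1 0
#' ...
#' ```
#'
#' Every line of the body holds one regulator-value combination (one column
#' per regulator, in the header's order) followed by the regulated node's
#' value at the next time step. Rows may appear in any order but must cover
#' every combination exactly once. An input node has an empty `regulators:`
#' line and a single body line holding its constant value.
#'
#' @param directory path containing one `.txt` file per node.
#' @param metadata provenance string stored on the returned network; defaults
#'   to the directory path.
#' @return a validated [logical_network].
#' @export
load_network <- function(directory, metadata = NULL) {
  if (!dir.exists(directory)) stop("no such directory: ", directory, call. = FALSE)
  files <- sort(list.files(directory, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0) stop("no node files (*.txt) found in ", directory, call. = FALSE)
  parsed <- lapply(files, parse_node_file)
  nodes <- dplyr::bind_rows(lapply(parsed, function(p) {
    tibble::tibble(name = p$name, arity = p$arity, regulators = list(p$regulators),
                   role = p$role)
  }))
  # resolve regulator references before table reindexing so the error is clear
  unknown <- setdiff(unique(unlist(nodes$regulators)), nodes$name)
  if (length(unknown) > 0) {
    stop("regulator(s) with no node file: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  arities <- stats::setNames(nodes$arity, nodes$name)
  tables <- stats::setNames(
    lapply(parsed, function(p) canonical_table(p, arities)),
    nodes$name
  )
  logical_network(nodes, tables,
                  metadata = if (is.null(metadata)) directory else metadata)
}

parse_node_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  header <- grepl("^[A-Za-z_]+:", lines)
  hv <- function(key, default = NULL) {
    hit <- grep(paste0("^", key, ":"), lines[header], value = TRUE)
    if (length(hit) == 0) {
      if (is.null(default)) stop(path, ": missing header '", key, ":'", call. = FALSE)
      return(default)
    }
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  name <- hv("node", sub("\\.txt$", "", basename(path)))
  body <- lines[!header]
  rows <- lapply(seq_along(body), function(k) {
    v <- suppressWarnings(as.integer(strsplit(body[k], "\\s+")[[1]]))
    if (anyNA(v)) stop(path, ": non-integer entry on table line ", k, call. = FALSE)
    v
  })
  regulators <- strsplit(hv("regulators", ""), "\\s+")[[1]]
  regulators <- regulators[nzchar(regulators)]
  width <- length(regulators) + 1L
  bad <- which(vapply(rows, length, integer(1)) != width)
  if (length(bad) > 0) {
    stop(path, ": table line ", bad[1], " has ", length(rows[[bad[1]]]),
         " entries, expected ", width, " (one per regulator plus the output)",
         call. = FALSE)
  }
  m <- do.call(rbind, rows)
  list(name = name,
       arity = as.integer(hv("arity")),
       role = hv("role", ""),
       regulators = regulators,
       combos = m[, seq_along(regulators), drop = FALSE],
       outputs = m[, width],
       path = path)
}

# Reorder parsed rows into canonical order, checking completeness and range.
canonical_table <- function(p, arities) {
  target_arity <- arities[[p$name]]
  bad_out <- which(p$outputs < 0L | p$outputs >= target_arity)
  if (length(bad_out) > 0) {
    stop(p$path, ": output value ", p$outputs[bad_out[1]], " out of range [0, ",
         target_arity, ") on table line ", bad_out[1], call. = FALSE)
  }
  k <- length(p$regulators)
  if (k == 0) {
    if (length(p$outputs) != 1) {
      stop(p$path, ": input node must have exactly one table line", call. = FALSE)
    }
    return(as.integer(p$outputs))
  }
  a <- arities[p$regulators]
  if (anyNA(a)) stop(p$path, ": unknown regulator arity", call. = FALSE)
  n_expected <- prod(a)
  if (any(p$combos < 0L) || any(sweep(p$combos, 2, a, `>=`))) {
    bad <- which(rowSums(p$combos < 0L | sweep(p$combos, 2, a, `>=`)) > 0)[1]
    stop(p$path, ": regulator value out of range on table line ", bad, call. = FALSE)
  }
  w <- rev(cumprod(rev(c(a[-1], 1))))
  idx <- as.vector(p$combos %*% w) + 1L
  if (anyDuplicated(idx)) {
    d <- idx[duplicated(idx)][1]
    stop(p$path, ": duplicated regulator combination (",
         paste(p$combos[match(d, idx), ], collapse = " "), ")", call. = FALSE)
  }
  if (length(idx) != n_expected) {
    missing_idx <- setdiff(seq_len(n_expected), idx)[1]
    combo <- decode_row(missing_idx - 1L, a)
    stop(p$path, ": incomplete table, missing combination (",
         paste(combo, collapse = " "), ")", call. = FALSE)
  }
  out <- integer(n_expected)
  out[idx] <- as.integer(p$outputs)
  out
}

decode_row <- function(r, arities) {
  k <- length(arities)
  out <- integer(k)
  for (j in k:1) {
    out[j] <- r %% arities[j]
    r <- r %/% arities[j]
  }
  out
}

#' Write a logical network as a directory of per-node truth-table files
#'
#' Inverse of [load_network()]: `load_network(save_network(net, d))`
#' reproduces `net` exactly, including regulator order and table contents.
#'
#' @inheritParams n_nodes
#' @param directory destination directory (created if absent).
#' @return `directory`, invisibly.
#' @export
save_network <- function(net, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  for (i in seq_len(n_nodes(net))) {
    nm <- net$nodes$name[i]
    regs <- net$nodes$regulators[[i]]
    grid <- regulator_grid(net, i)
    body <- if (ncol(grid) == 0) {
      as.character(net$tables[[nm]])
    } else {
      paste(apply(grid, 1, paste, collapse = " "), net$tables[[nm]])
    }
    writeLines(
      c(paste("node:", nm),
        paste("arity:", net$nodes$arity[i]),
        paste("role:", net$nodes$role[i]),
        paste("regulators:", paste(regs, collapse = " ")),
        body),
      file.path(directory, paste0(nm, ".txt"))
    )
  }
  invisible(directory)
}
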