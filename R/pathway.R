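# KEGG-module definition grammar:
#   space  - serial step (AND between steps; completeness counts these)
#   comma  - alternative (OR)
#   plus   - subunit within a complex (AND)
#   minus  - non-essential component (excluded from the requirement)
#   parens - grouping; a parenthesized sequence counts as ONE step
#   "--"   - internal gap token; ignored with a warning

#' Parse a KEGG-module definition
#'
#' @param definition Definition string over KO identifiers (`K` + 5 digits).
#' @return An expression tree of class `magniche_module_tree`: nested lists
#'   with node types `seq` (top level: one element per counted step), `or`,
#'   `complex` (subunits with an `optional` flag), and `leaf`.
#' @export
#' @examples
#' tree <- parse_module_definition("(K00001+K00002) K00003,K00004")
#' length(tree$steps) # 2
parse_module_definition <- function(definition) {
  if (!is.character(definition) || length(definition) != 1 ||
      is.na(definition) || !nzchar(trimws(definition))) {
    abort("module definition must be a non-empty string")
  }
  src <- definition
  if (grepl("--", src, fixed = TRUE)) {
    warn("module definition contains '--' gap token(s); ignored")
    src <- gsub("\\s*--\\s*", " ", src)
    src <- trimws(gsub("\\s+", " ", src))
  }
  st <- new.env(parent = emptyenv())
  st$s <- src
  st$pos <- 1L
  st$n <- nchar(src)

  peek <- function() if (st$pos > st$n) "" else substr(st$s, st$pos, st$pos)
  advance <- function() st$pos <- st$pos + 1L
  perr <- function(msg) {
    abort(sprintf("module definition parse error at position %d: %s (in \"%s\")",
                  st$pos, msg, definition))
  }
  skip_ws <- function() while (peek() == " ") advance()

  parse_seq <- function() {
    steps <- list()
    optional <- logical()
    repeat {
      skip_ws()
      if (peek() %in% c("", ")")) break
      # a minus at the start of a step marks the whole step optional
      opt <- FALSE
      if (peek() == "-") {
        advance()
        opt <- TRUE
      }
      steps[[length(steps) + 1L]] <- parse_step()
      optional[length(steps)] <- opt
    }
    if (length(steps) == 0) perr("empty sequence")
    list(type = "seq", steps = steps, optional = optional)
  }

  parse_step <- function() {
    alts <- list(parse_complex())
    while (peek() == ",") {
      advance()
      if (peek() %in% c("", ")", " ", ",")) perr("empty alternative")
      alts[[length(alts) + 1L]] <- parse_complex()
    }
    if (length(alts) == 1) alts[[1]] else list(type = "or", alts = alts)
  }

  parse_complex <- function() {
    parts <- list(parse_unit())
    optional <- FALSE
    while (peek() %in% c("+", "-")) {
      op <- peek()
      advance()
      if (!peek() %in% c("K", "(")) perr(paste0("expected KO or '(' after '", op, "'"))
      parts[[length(parts) + 1L]] <- parse_unit()
      optional[length(parts)] <- (op == "-")
    }
    if (length(parts) == 1) {
      parts[[1]]
    } else {
      list(type = "complex", parts = parts, optional = optional)
    }
  }

  parse_unit <- function() {
    ch <- peek()
    if (ch == "(") {
      advance()
      inner <- parse_seq()
      if (peek() != ")") perr("unbalanced parentheses: expected ')'")
      advance()
      # a single-step group is just that step; keep seq only for true
      # nested sequences (which count as one step at the outer level)
      if (length(inner$steps) == 1 && !inner$optional[1]) {
        inner$steps[[1]]
      } else {
        inner
      }
    } else if (ch == "K") {
      ko <- substr(st$s, st$pos, st$pos + 5L)
      if (!grepl("^K\\d{5}$", ko)) perr("malformed KO identifier")
      st$pos <- st$pos + 6L
      list(type = "leaf", ko = ko)
    } else {
      perr(paste0("unexpected character '", ch, "'"))
    }
  }

  tree <- parse_seq()
  skip_ws()
  if (st$pos <= st$n) perr("unbalanced parentheses: unexpected ')'")
  structure(tree, class = "magniche_module_tree")
}

eval_node <- function(node, kos) {
  switch(node$type,
    leaf = node$ko %in% kos,
    or = any(vapply(node$alts, eval_node, logical(1), kos = kos)),
    complex = {
      opt <- node$optional
      req <- node$parts[!opt]
      if (length(req) == 0) TRUE
      else all(vapply(req, eval_node, logical(1), kos = kos))
    },
    seq = {
      opt <- node$optional
      req <- node$steps[!opt]
      if (length(req) == 0) TRUE
      else all(vapply(req, eval_node, logical(1), kos = kos))
    },
    abort(paste0("unknown node type: ", node$type))
  )
}

deparse_node <- function(node, top = FALSE) {
  out <- switch(node$type,
    leaf = node$ko,
    or = paste(vapply(node$alts, deparse_node, character(1)), collapse = ","),
    complex = {
      ops <- ifelse(node$optional[-1], "-", "+")
      # OR nodes bind more loosely than '+'/'-', so re-parenthesize them
      parts <- vapply(node$parts, function(p) {
        s <- deparse_node(p)
        if (p$type == "or") paste0("(", s, ")") else s
      }, character(1))
      paste0(parts[1], paste0(ops, parts[-1], collapse = ""))
    },
    seq = {
      steps <- vapply(seq_along(node$steps), function(i) {
        s <- deparse_node(node$steps[[i]])
        if (node$optional[i]) paste0("-", s) else s
      }, character(1))
      body <- paste(steps, collapse = " ")
      if (top) body else paste0("(", body, ")")
    }
  )
  out
}

#' @export
format.magniche_module_tree <- function(x, ...) deparse_node(x, top = TRUE)

#' @export
print.magniche_module_tree <- function(x, ...) {
  cat("<module definition> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Module completeness for one KO set
#'
#' A counted step is satisfied iff its expression evaluates true given the
#' KO set (OR: any branch; complex: all non-optional subunits; nested
#' groups recursively). Completeness is `100 * satisfied / total` over the
#' required (non-optional) top-level steps; a module whose steps are all
#' optional is trivially 100% complete.
#'
#' @param tree A parsed definition ([parse_module_definition()]) or a
#'   definition string.
#' @param kos Character vector of KO identifiers present.
#' @return List with `n_steps`, `n_satisfied`, `completeness` (percent).
#' @export
module_completeness <- function(tree, kos) {
  if (is.character(tree)) tree <- parse_module_definition(tree)
  steps <- tree$steps[!tree$optional]
  n <- length(steps)
  if (n == 0) {
    return(list(n_steps = 0L, n_satisfied = 0L, completeness = 100))
  }
  sat <- sum(vapply(steps, eval_node, logical(1), kos = kos))
  list(n_steps = n, n_satisfied = as.integer(sat),
       completeness = 100 * sat / n)
}

#' Per-genome module completeness report
#'
#' Scores every module against every MAG's KO set (annotation count >= 1)
#' and flags modules strictly above the reporting threshold (default 75%).
#' Additional genomes given as plain KO-identifier vectors (e.g. annotation
#' sets of the host animal and its algal symbiont) are scored alongside the
#' MAGs.
#'
#' @param modules Module-definition tibble (`module_id`, `name`,
#'   `definition`).
#' @param annotations Wide KO annotation tibble (`mag_id` + KO columns).
#' @param threshold Strict completeness threshold for flagging.
#' @param extra_genomes Optional named list of KO character vectors.
#' @return Tibble of class `magniche_completeness`: `mag_id`, `module_id`,
#'   `name`, `n_steps`, `n_satisfied`, `completeness`, `flagged`.
#' @export
completeness_report <- function(modules, annotations, threshold = 75,
                                extra_genomes = NULL) {
  trees <- lapply(modules$definition, parse_module_definition)
  feats <- setdiff(names(annotations), "mag_id")
  pres <- as.matrix(as_tibble(annotations)[feats]) >= 1
  ko_sets <- lapply(seq_len(nrow(annotations)), function(i) feats[pres[i, ]])
  names(ko_sets) <- annotations$mag_id
  if (!is.null(extra_genomes)) ko_sets <- c(ko_sets, extra_genomes)

  res <- purrr::map_dfr(names(ko_sets), function(g) {
    purrr::map_dfr(seq_along(trees), function(j) {
      mc <- module_completeness(trees[[j]], ko_sets[[g]])
      tibble(mag_id = g, module_id = modules$module_id[j],
             name = modules$name[j], n_steps = mc$n_steps,
             n_satisfied = mc$n_satisfied, completeness = mc$completeness)
    })
  })
  res <- dplyr::mutate(res, flagged = .data$completeness > threshold)
  class(res) <- c("magniche_completeness", class(res))
  res
}
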