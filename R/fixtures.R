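# Named circuit fixtures: the minimal building-block circuits (self-loop,
# mutual feedback variants, feedforward loops) and their combinations and
# interactions, with parameters chosen so that each circuit sits in its
# characteristic dynamical regime (bistability, pulse, damped oscillation,
# ...). Parameter choices are documented in the package vignette.

edge_row <- function(from, to, sign, k = 0.5, n = 2) {
  data.frame(from = from, to = to, sign = sign, k = k, n = n,
             stringsAsFactors = FALSE)
}

#' Built-in circuit fixtures
#'
#' Returns a ready-to-simulate [build_model()] circuit for a named fixture:
#'
#' * `"SL"` — single node with a positive self-loop (bistable switch).
#' * `"TMFL"` — toggle switch: two mutually repressing nodes.
#' * `"LMFL"` — Lock-ON: two mutually activating nodes.
#' * `"OMFL"` — oscillator: activator-repressor mutual feedback (damped
#'   oscillations).
#' * `"TMFL+SL"`, `"LMFL+SL"`, `"OMFL+SL"` — the same circuits with positive
#'   self-loops on both nodes (AND gating of self and partner input).
#' * `"C1FFL"`, `"I1FFL"` — coherent / incoherent type-1 feedforward loops
#'   with a step input X (AND gate at the output).
#' * `"C1FFL+SLy"`, `"I1FFL+SLy"` — feedforward loops with a positive
#'   self-loop on the intermediate node Y.
#' * `"DMF2+"` — two double mutual feedback circuits (X-Y and Y-Z mutual
#'   pairs plus an X-to-Z edge) sharing the X-to-Z edge, all activating.
#' * `"DMF2-"` — the same combination with the shared X-to-Z edge
#'   repressing (in-phase synchronized oscillations of Y and W).
#' * `"LOOP3-pair"` — two three-node loops sharing an edge, all edges
#'   activating except one repression (anti-phase synchronization).
#' * `"FFL-pair"` — a coherent FFL activating an incoherent FFL which
#'   represses it back (emergent oscillations).
#'
#' @param name fixture name (see above); `circuit_fixtures()` lists them.
#' @param input optional named numeric vector overriding input step levels.
#' @return an `hm_circuit`.
#' @export
circuit_fixture <- function(name, input = NULL) {
  fx <- switch(name,
    "SL" = build_model(
      nodes = "X",
      edges = edge_row("X", "X", "+", k = 0.4)),
    "TMFL" = build_model(
      nodes = c("X", "Y"),
      edges = rbind(edge_row("Y", "X", "-", k = 0.3),
                    edge_row("X", "Y", "-", k = 0.3))),
    "LMFL" = build_model(
      nodes = c("X", "Y"),
      edges = rbind(edge_row("Y", "X", "+", k = 0.3),
                    edge_row("X", "Y", "+", k = 0.3))),
    "OMFL" = build_model(
      nodes = c("X", "Y"),
      edges = rbind(edge_row("Y", "X", "+", k = 0.3, n = 4),
                    edge_row("X", "Y", "-", k = 0.3, n = 4))),
    "TMFL+SL" = build_model(
      nodes = c("X", "Y"),
      edges = rbind(edge_row("Y", "X", "-", k = 0.3),
                    edge_row("X", "Y", "-", k = 0.3),
                    edge_row("X", "X", "+", k = 0.3),
                    edge_row("Y", "Y", "+", k = 0.3))),
    "LMFL+SL" = build_model(
      nodes = c("X", "Y"),
      edges = rbind(edge_row("Y", "X", "+", k = 0.3),
                    edge_row("X", "Y", "+", k = 0.3),
                    edge_row("X", "X", "+", k = 0.3),
                    edge_row("Y", "Y", "+", k = 0.3))),
    "OMFL+SL" = build_model(
      nodes = c("X", "Y"),
      edges = rbind(edge_row("Y", "X", "+", k = 0.3, n = 4),
                    edge_row("X", "Y", "-", k = 0.3, n = 4),
                    edge_row("X", "X", "+", k = 0.15),
                    edge_row("Y", "Y", "+", k = 0.15))),
    "C1FFL" = build_model(
      nodes = c("X", "Y", "Z"),
      edges = rbind(edge_row("X", "Y", "+", k = 0.3),
                    edge_row("X", "Z", "+", k = 0.3),
                    edge_row("Y", "Z", "+", k = 0.3)),
      inputs = c(X = 0.5)),
    "I1FFL" = build_model(
      nodes = c("X", "Y", "Z"),
      edges = rbind(edge_row("X", "Y", "+", k = 0.3),
                    edge_row("X", "Z", "+", k = 0.05),
                    edge_row("Y", "Z", "-", k = 0.15)),
      inputs = c(X = 0.5)),
    "C1FFL+SLy" = build_model(
      nodes = c("X", "Y", "Z"),
      edges = rbind(edge_row("X", "Y", "+", k = 0.3),
                    edge_row("Y", "Y", "+", k = 0.3),
                    edge_row("X", "Z", "+", k = 0.3),
                    edge_row("Y", "Z", "+", k = 0.3)),
      inputs = c(X = 0.5)),
    "I1FFL+SLy" = build_model(
      nodes = c("X", "Y", "Z"),
      edges = rbind(edge_row("X", "Y", "+", k = 0.3),
                    edge_row("Y", "Y", "+", k = 0.3),
                    edge_row("X", "Z", "+", k = 0.05),
                    edge_row("Y", "Z", "-", k = 0.15)),
      inputs = c(X = 0.5)),
    "DMF2+" = dmf2_fixture("+"),
    "DMF2-" = dmf2_fixture("-"),
    "LOOP3-pair" = build_model(
      nodes = c("X", "Y", "Z", "W"),
      edges = rbind(edge_row("X", "Y", "+", k = 0.3, n = 4),
                    edge_row("Y", "Z", "-", k = 0.3, n = 4),
                    edge_row("Z", "X", "+", k = 0.3, n = 4),
                    edge_row("Y", "W", "+", k = 0.3, n = 4),
                    edge_row("W", "X", "+", k = 0.3, n = 4)),
      beta = 1.5, gate = "AND"),
    "FFL-pair" = build_model(
      nodes = c("X", "Y", "Z", "W", "V", "U"),
      edges = rbind(edge_row("X", "Y", "+", k = 0.3),
                    edge_row("X", "Z", "+", k = 0.3),
                    edge_row("Y", "Z", "+", k = 0.3),
                    edge_row("W", "V", "+", k = 0.3),
                    edge_row("W", "U", "+", k = 0.3),
                    edge_row("V", "U", "-", k = 0.3),
                    edge_row("Z", "W", "+", k = 0.3),
                    edge_row("U", "X", "-", k = 0.3)),
      gate = "OR"),
    stop("unknown fixture '", name, "'; see circuit_fixtures()")
  )
  if (!is.null(input)) {
    fx <- build_model(fx$nodes, fx$edges, beta = fx$beta, alpha = fx$alpha,
                      gate = fx$gate, inputs = input)
  }
  fx
}

# two double-mutual-feedback motifs (X-Y, Y-Z mutual, X->Z directed) sharing
# the X->Z edge; the second motif contributes the X-W and W-Z mutual pairs.
# The repressing variant oscillates when X turns over faster than its
# partners (negative loop X -| Z -> Y -> X with slow positive feedback).
dmf2_fixture <- function(xz_sign) {
  build_model(
    nodes = c("X", "Y", "Z", "W"),
    edges = rbind(edge_row("X", "Y", "+", k = 0.15, n = 4),
                  edge_row("Y", "X", "+", k = 0.15, n = 4),
                  edge_row("Y", "Z", "+", k = 0.15, n = 4),
                  edge_row("Z", "Y", "+", k = 0.15, n = 4),
                  edge_row("X", "W", "+", k = 0.15, n = 4),
                  edge_row("W", "X", "+", k = 0.15, n = 4),
                  edge_row("W", "Z", "+", k = 0.15, n = 4),
                  edge_row("Z", "W", "+", k = 0.15, n = 4),
                  edge_row("X", "Z", xz_sign, k = 0.3, n = 4)),
    alpha = c(X = 1, Y = 0.3, Z = 0.3, W = 0.3),
    gate = "AND")
}

#' @rdname circuit_fixture
#' @export
circuit_fixtures <- function() {
  c("SL", "TMFL", "LMFL", "OMFL", "TMFL+SL", "LMFL+SL", "OMFL+SL",
    "C1FFL", "I1FFL", "C1FFL+SLy", "I1FFL+SLy",
    "DMF2+", "DMF2-", "LOOP3-pair", "FFL-pair")
}

#' Read / write circuit specification files
#'
#' Plain-text circuit format, one declaration per line:
#' ```
#' node X [beta alpha]
#' input X level
#' edge X Y + [k n]
#' gate Y AND|OR
#' ```
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_circuit()` returns an `hm_circuit`.
#' @export
read_circuit <- function(path) {
  lines <- readLines(path)
  nodes <- character(0)
  beta <- numeric(0)
  alpha <- numeric(0)
  gate <- character(0)
  inputs <- numeric(0)
  edges <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    kind <- toks[1]
    if (kind == "node") {
      nodes <- c(nodes, toks[2])
      if (length(toks) >= 4) {
        beta[toks[2]] <- as.numeric(toks[3])
        alpha[toks[2]] <- as.numeric(toks[4])
      }
    } else if (kind == "input") {
      nodes <- union(nodes, toks[2])
      inputs[toks[2]] <- as.numeric(toks[3])
    } else if (kind == "edge") {
      k <- if (length(toks) >= 5) as.numeric(toks[5]) else 0.5
      n <- if (length(toks) >= 6) as.numeric(toks[6]) else 2
      edges[[length(edges) + 1]] <- edge_row(toks[2], toks[3], toks[4], k, n)
    } else if (kind == "gate") {
      gate[toks[2]] <- toks[3]
    } else {
      stop("unrecognized declaration '", kind, "' at line ", i)
    }
  }
  build_model(nodes, do.call(rbind, edges),
              beta = if (length(beta)) beta else 1,
              alpha = if (length(alpha)) alpha else 1,
              gate = if (length(gate)) gate else "AND",
              inputs = if (length(inputs)) inputs else NULL)
}

#' @rdname read_circuit
#' @param model an `hm_circuit`.
#' @export
write_circuit <- function(model, path) {
  stopifnot(inherits(model, "hm_circuit"))
  lines <- character(0)
  for (nd in model$dynamic) {
    lines <- c(lines, sprintf("node %s %g %g", nd,
                              model$beta[[nd]], model$alpha[[nd]]))
  }
  for (nm in names(model$inputs)) {
    lines <- c(lines, sprintf("input %s %g", nm, model$inputs[[nm]]))
  }
  if (nrow(model$edges) > 0) {
    for (r in seq_len(nrow(model$edges))) {
      e <- model$edges[r, ]
      lines <- c(lines, sprintf("edge %s %s %s %g %g",
                                e$from, e$to, e$sign, e$k, e$n))
    }
  }
  for (nd in model$dynamic) {
    lines <- c(lines, sprintf("gate %s %s", nd, model$gate[[nd]]))
  }
  writeLines(lines, path)
  invisible(model)
}
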