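# Independent numerical oracles used to cross-check the implementation.

# Exhaustive tripartite triangle enumeration over every (taxon, module,
# score) combination of the node table -- independent of the
# adjacency-driven enumeration in the package.
brute_force_triangles <- function(net, pp_node) {
  keys <- paste(pmin(net$edges$node_a, net$edges$node_b),
                pmax(net$edges$node_a, net$edges$node_b))
  has_edge <- function(a, b) paste(pmin(a, b), pmax(a, b)) %in% keys
  taxa <- net$nodes$id[net$nodes$modality == "T"]
  mods <- net$nodes$id[net$nodes$modality == "M"]
  out <- expand.grid(taxon = taxa, module = mods,
                     stringsAsFactors = FALSE)
  ok <- has_edge(out$taxon, out$module) &
    has_edge(out$taxon, pp_node) & has_edge(out$module, pp_node)
  out <- out[ok, , drop = FALSE]
  out <- out[order(out$taxon, out$module), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Euler integral representation of the Gauss hypergeometric function,
# valid for c > b > 0: an independent check of the series evaluation.
hyp2f1_euler <- function(a, b, c, x) {
  f <- function(t) t^(b - 1) * (1 - t)^(c - b - 1) * (1 - x * t)^(-a)
  I <- integrate(f, 0, 1, rel.tol = 1e-10)
  exp(lgamma(c) - lgamma(b) - lgamma(c - b)) * I$value
}

# Textbook normal-equations least squares, used against the QR-based
# adjustment path.
normal_equations_residuals <- function(Y, X) {
  D <- cbind(1, X)
  beta <- solve(t(D) %*% D, t(D) %*% Y)
  Y - D %*% beta
}
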