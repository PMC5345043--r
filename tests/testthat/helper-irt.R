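# quadrature oracle: EAP of theta | response pattern under known item
# parameters, theta ~ N(0,1), via 61-node Gauss-Hermite
gh_eap_oracle <- function(patterns, a, b, n_nodes = 61) {
  gq <- statmod::gauss.quad.prob(n_nodes, dist = "normal")
  sapply(seq_len(nrow(patterns)), function(r) {
    lik <- rep(1, n_nodes)
    for (i in seq_along(a)) {
      p1 <- pnorm(a[i] * gq$nodes - b[i])
      lik <- lik * (if (patterns[r, i] == 1) p1 else 1 - p1)
    }
    sum(gq$weights * lik * gq$nodes) / sum(gq$weights * lik)
  })
}

make_panel <- function(mat, wave = 1L) {
  rows <- expand.grid(person_id = seq_len(nrow(mat)),
                      item = seq_len(ncol(mat)))
  panel <- data.frame(person_id = rows$person_id, wave = wave,
                      item_id = sprintf("item%02d", rows$item),
                      response = mat[cbind(rows$person_id, rows$item)],
                      status = "observed")
  class(panel) <- c("response_panel", "data.frame")
  panel
}

toy_catalog <- function(n_items, n_cat = 2L, n_waves = 1L) {
  structure(list(
    items = data.frame(item_id = sprintf("item%02d", seq_len(n_items)),
                       n_cat = n_cat, direction = "higher_is_worse",
                       factor = 1L, factor2 = NA_integer_),
    availability = matrix(TRUE, n_items, n_waves,
                          dimnames = list(sprintf("item%02d", seq_len(n_items)),
                                          paste0("wave", seq_len(n_waves))))),
    class = "item_catalog")
}
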