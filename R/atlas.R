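#' Build a synthetic parcel atlas
#'
#' Partitions `V` cortical vertices into `K` index-contiguous parcels, one per
#' network. The atlas plays the role a 17-network surface parcellation plays in
#' real data: it seeds the dual regression and identifies which network is
#' treated as the salience network. Parcel sizes are drawn (deterministically
#' given `seed`) around `V / K` so that parcels are unequal, as real
#' parcellations are, while every vertex receives exactly one label.
#'
#' @param V Number of vertices (default 20484, a 10k-per-hemisphere surface).
#' @param K Number of networks/parcels (default 17).
#' @param seed Integer seed controlling parcel sizes.
#' @param salience_index Which network is the salience network (default 8;
#'   any value in `1..K` is legal, the geometry carries no meaning).
#'
#' @return An object of class `atlas_spec` with fields `V`, `K`, `labels`
#'   (integer vector of length `V` in `1..K`) and `salience_index`.
#' @export
make_parcel_atlas <- function(V = 20484L, K = 17L, seed = 1L,
                              salience_index = min(8L, K)) {
  V <- as.integer(V); K <- as.integer(K)
  if (K > V) stop_config("K = %d parcels cannot exceed V = %d vertices", K, V)
  if (K < 1L || V < 1L) stop_config("V and K must be positive")
  if (salience_index < 1L || salience_index > K) {
    stop_config("salience_index must lie in 1..%d", K)
  }
  sizes <- with_seed(seed, {
    if (K == V) {
      rep(1L, K)
    } else {
      # jittered proportions, floored at one vertex per parcel
      w <- stats::rgamma(K, shape = 20, rate = 1)
      s <- pmax(1L, as.integer(floor(w / sum(w) * V)))
      # distribute the remainder deterministically over the first parcels
      excess <- V - sum(s)
      i <- 1L
      while (excess != 0L) {
        step <- if (excess > 0L) 1L else -1L
        if (s[i] + step >= 1L) {
          s[i] <- s[i] + step
          excess <- excess - step
        }
        i <- if (i == K) 1L else i + 1L
      }
      s
    }
  })
  labels <- rep.int(seq_len(K), times = sizes)
  structure(
    list(V = V, K = K, labels = labels, salience_index = as.integer(salience_index)),
    class = "atlas_spec"
  )
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("<atlas_spec> %d vertices, %d networks (salience = network %d)\n",
              x$V, x$K, x$salience_index))
  invisible(x)
}

check_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "atlas_spec"))
  if (length(atlas$labels) != atlas$V ||
      !all(atlas$labels %in% seq_len(atlas$K))) {
    stop_config("atlas labels do not partition the %d vertices", atlas$V)
  }
  invisible(atlas)
}
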