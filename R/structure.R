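# Net structure matrices: Y_sigma distributes transition actions over the
# edges of the event handlers that execute them; Z_m collects token changes
# on place arcs into places; Y_m distributes place tokens over intensity
# edges; Z_lambda collects intensity changes on transition arcs into
# transitions.

#' Structure matrices of a Flexible Net
#'
#' Returns the four 0/±1 incidence-style matrices of the state equations:
#' `Y_sigma` (transitions x event edges, 1 where the edge touches the
#' transition), `Z_m` (places x event arcs, -1 for consumption arcs, +1 for
#' production arcs), `Y_m` (places x intensity edges) and `Z_lambda`
#' (transitions x intensity arcs, -1 for intensity-decrease arcs, +1 for
#' increase arcs).  Silent (fake) transitions are included as rows of
#' `Y_sigma` and `Z_lambda`.
#'
#' @param net an `fn_net`.
#' @return list with matrices `Y_sigma`, `Z_m`, `Y_m`, `Z_lambda`, all with
#'   dimnames in canonical order.
#' @export
structure_matrices <- function(net) {
  P <- net$places
  Tt <- net$all_transitions
  Y_sigma <- matrix(0, length(Tt), nrow(net$EVT),
                    dimnames = list(Tt, net$EVT$id))
  for (i in seq_len(nrow(net$EVT))) {
    Y_sigma[net$EVT$transition[i], i] <- 1
  }
  Z_m <- matrix(0, length(P), nrow(net$EVP),
                dimnames = list(P, net$EVP$id))
  for (i in seq_len(nrow(net$EVP))) {
    Z_m[net$EVP$place[i], i] <- if (net$EVP$dir[i] == "in") -1 else 1
  }
  Y_m <- matrix(0, length(P), nrow(net$ESP),
                dimnames = list(P, net$ESP$id))
  for (i in seq_len(nrow(net$ESP))) {
    if (!net$ESP$fake[i]) Y_m[net$ESP$place[i], i] <- 1
  }
  Z_lambda <- matrix(0, length(Tt), nrow(net$EST),
                     dimnames = list(Tt, net$EST$id))
  for (i in seq_len(nrow(net$EST))) {
    Z_lambda[net$EST$transition[i], i] <-
      if (net$EST$dir[i] == "in") -1 else 1
  }
  list(Y_sigma = Y_sigma, Z_m = Z_m, Y_m = Y_m, Z_lambda = Z_lambda)
}
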