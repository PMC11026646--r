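# Small, fast parameter sets shared across tests. Scene geometry is kept
# tiny; physically calibrated quantities keep their real-world values.

quick_params <- function(...) {
  defaults <- list(n_frames = 20L, tunnel_length_um = 40,
                   n_stationary = 4L, n_motile = 1L, speeds_um_s = 0.6,
                   duration_s = 10, n_channels = 3L, seed = 1L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# direct flood-fill labelling, used as an oracle for the C++ labeller
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8L)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ] else
      data.frame(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!mask[rr, cc] || lab[rr, cc] > 0L) next
    cur <- cur + 1L
    queue <- list(c(rr, cc)); lab[rr, cc] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        r2 <- p[1] + nbrs$dr[k]; c2 <- p[2] + nbrs$dc[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}
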