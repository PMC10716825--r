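# Independent oracles the implementation is checked against.

# Surveyor's (shoelace) formula on the Cartesian vertices of the polar
# projection: vertex i at radius d_i, angle (i-1) * 2*pi/n.
shoelace_area <- function(d) {
  n <- length(d)
  theta <- (seq_len(n) - 1) * 2 * pi / n
  x <- d * cos(theta)
  y <- d * sin(theta)
  0.5 * abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
}

# Pairwise-comparison AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half.
brute_auc <- function(y_true, y_score) {
  pos <- y_score[y_true == 1]
  neg <- y_score[y_true == 0]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

random_metric_vector <- function(n) {
  stats::setNames(stats::runif(n), paste0("m", seq_len(n)))
}
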