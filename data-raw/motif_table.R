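# Derives the 169-row configuration -> motif-class table shipped in
# inst/extdata/motif_configurations.csv.
#
# A configuration is the pair (weak order of the three node times (0, t1, t2),
# weak order of the three node channels (0, n1, n2)); 13 weak orders of three
# items per axis give 13 x 13 = 169 configurations. The collapse into the 14
# motif classes keeps temporal direction (divergence XI vs convergence XII)
# and collapses spatial reflection (channel order in a raster is arbitrary).

sign_sym <- function(x) c("-", "0", "+")[sign(x) + 2L]

weak_order_code <- function(a, b) {
  # weak order of (0, a, b), encoded by the three pairwise comparisons
  paste0(sign_sym(a), sign_sym(b), sign_sym(b - a))
}

class_of_quadruple <- function(n1, t1, n2, t2) {
  b_is_a <- n1 == 0 && t1 == 0
  c_is_a <- n2 == 0 && t2 == 0
  b_is_c <- n1 == n2 && t1 == t2
  if (b_is_a && c_is_a) return("0")
  if (b_is_a || c_is_a || b_is_c) {
    # exactly two distinct spatiotemporal points
    if (b_is_a) { dn <- n2; dt <- t2 } else { dn <- n1; dt <- t1 }
    if (dn == 0) return("I")    # one channel, two times: autocorrelation
    if (dt == 0) return("III")  # two channels, one time: synchrony
    return("V")                 # cross-correlation
  }
  ch <- c(0, n1, n2); tt <- c(0, t1, t2)
  nch <- length(unique(ch)); nt <- length(unique(tt))
  if (nch == 1) return("II")                 # three spikes on one channel
  if (nt == 1) return("IV")                  # three-channel synchrony
  if (nch == 3 && nt == 3) return("XIII")    # feedforward chain
  if (nch == 3) {
    # three channels, two times: a synchronous pair plus a lone spike
    lone_t <- tt[!(duplicated(tt) | duplicated(tt, fromLast = TRUE))]
    pair_t <- tt[duplicated(tt)][1]
    return(if (lone_t < pair_t) "XI" else "XII")  # divergence / convergence
  }
  dup_ch <- ch[duplicated(ch)][1]
  lone_t <- tt[ch != dup_ch]
  pair_ts <- tt[ch == dup_ch]
  if (nt == 3) {
    # two channels, three times: doubled channel spikes twice
    if (lone_t > min(pair_ts) && lone_t < max(pair_ts)) return("IX")  # feedback
    return(if (lone_t < min(pair_ts)) "VIII" else "X")
  }
  # two channels, two times (L-shape): lone-channel spike synchronous with
  # the earlier (VI) or later (VII) spike of the doubled channel
  if (lone_t == min(pair_ts)) "VI" else "VII"
}

grid <- expand.grid(n1 = -2:2, t1 = -2:2, n2 = -2:2, t2 = -2:2)
grid$temporal_order_code <- mapply(weak_order_code, grid$t1, grid$t2)
grid$spatial_order_code <- mapply(weak_order_code, grid$n1, grid$n2)
grid$class_label <- mapply(class_of_quadruple, grid$n1, grid$t1, grid$n2, grid$t2)

tab <- unique(grid[, c("temporal_order_code", "spatial_order_code", "class_label")])
stopifnot(nrow(tab) == 169)
# class is a function of the configuration pair
stopifnot(!anyDuplicated(tab[, 1:2]))
stopifnot(length(unique(tab$class_label)) == 14)

tab <- tab[order(tab$temporal_order_code, tab$spatial_order_code), ]
tab$config_id <- seq_len(nrow(tab))
tab <- tab[, c("config_id", "temporal_order_code", "spatial_order_code", "class_label")]

print(sort(table(tab$class_label)))
write.csv(tab, "inst/extdata/motif_configurations.csv", row.names = FALSE, quote = FALSE)
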