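# Shared fixtures, built in code at test time.

# small untrained network, cached per session
test_net <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- build_network(scale = 8L, seed = 101L)
    memo
  }
})

# force the classifier's vote by biasing the output layer: handy for
# exercising the segmentation gate deterministically
rig_network <- function(net, vote = c("tumor", "not_tumor")) {
  vote <- match.arg(vote)
  net$params$b7 <- if (vote == "tumor") c(-20, 20) else c(20, -20)
  net
}

# reproducible random binary mask with roughly `p` coverage
random_mask <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  matrix(as.integer(runif(n * n) < p), n, n)
}

# normalized phantom pixels ready for the network
phantom_input <- function(seed = 5, tumor_prob = 1) {
  ph <- generate_phantom(phantom_spec(tumor_prob = tumor_prob), seed = seed)
  list(x = zscore_normalize(ph$slice)$pixels,
       raw = ph$slice$pixels,
       mask = ph$mask, label = ph$label)
}
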