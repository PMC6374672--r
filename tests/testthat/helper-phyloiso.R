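# Shared generators and independent oracles for the test suite.

# Random non-ultrametric tree with positive branch lengths.
randomTree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 2)
  tr$root.edge <- NULL
  tr
}

# Independent fair-proportion oracle: iterate edges, find each edge's
# descendant tips by its own recursion, and add L/n to each of them.
bruteForceED <- function(tree) {
  n <- ape::Ntip(tree)
  tipsUnder <- function(node) {
    if (node <= n) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tipsUnder))
  }
  ed <- stats::setNames(numeric(n), tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tipsUnder(tree$edge[e, 2])
    ed[tips] <- ed[tips] + tree$edge.length[e] / length(tips)
  }
  ed
}

# The worked 5-tip tree used across scenario tests.
workedTree <- function() readNewick("((H:1,X:1):3,(Y:2,(Z:1,W:1):1):2);")

workedStatuses <- function(cats = c(H = "LC", X = "LC", Y = "LC",
                                    Z = "LC", W = "LC")) {
  data.frame(species = names(cats), category = unname(cats),
             stringsAsFactors = FALSE)
}
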