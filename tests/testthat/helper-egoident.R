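# Shared fixtures, built in code.

# complete 8-alter graph at a 4:4 ratio
complete_44 <- function() generate_network(8, 4, 28, seed = 1)

# tiny hand-built net: A alters {0,1}, B alter {2}, ties {(0,1),(0,2)}
hand_net_aab <- function() {
  ego_network(c("A", "A", "B"), ties = rbind(c(0, 1), c(0, 2)))
}

# 4 A friends (0..3) + 4 A colleagues (4..7), complete bipartite across the
# friend/colleague split (16 cross ties)
friends_colleagues_complete <- function() {
  ties <- as.matrix(expand.grid(0:3, 4:7))
  ego_network(rep("A", 8), ties = ties,
              domains = rep(c("friend", "colleague"), each = 4))
}

# number of within-culture ties of a network, by direct enumeration
n_within_culture_ties <- function(net) {
  if (nrow(net$ties) == 0) return(0L)
  sum(net$cultures[net$ties[, 1] + 1] == net$cultures[net$ties[, 2] + 1])
}

expect_state_equal <- function(state, id_a, id_b, tol = 1e-9) {
  expect_equal(state$id_a, id_a, tolerance = tol)
  expect_equal(state$id_b, id_b, tolerance = tol)
}
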