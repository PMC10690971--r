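test_that("state space contains the primary states, tunnels and absorbers", {
  sp <- default_space()
  # ten primary (pure-history) states
  primary <- c("Non-fatal MI", "Non-fatal MI 2+", "Non-fatal stroke",
               "Non-fatal stroke 2+", "Post-MI", "Post-MI 2+",
               "Post-stroke", "Post-stroke 2+", "CV death", "Non-CV death")
  expect_true(all(primary %in% sp$name))
  expect_true(sp$tunnel[sp$name == "Non-fatal MI"])
  expect_true(all(sp$tunnel[sp$phase %in% c("acute_MI", "acute_stroke")]))
  expect_false(any(sp$tunnel[sp$phase == "chronic"]))
  # revascularization is a procedure, never a state
  expect_false(any(grepl("evascular", sp$name)))
  # death states absorbing, nothing else
  expect_identical(sp$name[sp$absorbing], c("CV death", "Non-CV death"))
  # composite components have >= 2 primitive histories
  comp <- sp[sp$category == "composite", ]
  expect_true(all(lengths(comp$components) >= 2))
})

test_that("composition is commutative and rejects death/acute-acute pairs", {
  sp <- default_space()
  expect_identical(compose_state(sp, "post_MI", "post_stroke"),
                   "Post-MI + Post-stroke")
  # exhaustive commutativity over all valid pairs
  prim <- c("post_MI", "post_MI_2plus", "post_stroke", "post_stroke_2plus",
            "acute_MI", "acute_MI_2plus", "acute_stroke",
            "acute_stroke_2plus")
  for (a in prim) for (b in prim) {
    ab <- tryCatch(compose_state(sp, a, b), error = function(e) e)
    ba <- tryCatch(compose_state(sp, b, a), error = function(e) e)
    if (inherits(ab, "error")) expect_s3_class(ba, "error")
    else expect_identical(ab, ba)
  }
  expect_error(compose_state(sp, "post_MI", "CV_death"), "absorbing")
  expect_error(compose_state(sp, "acute_MI", "acute_stroke"), "two acute")
  expect_error(compose_state(sp, "post_MI", "post_MI_2plus"),
               "distinct event types")
})

test_that("acute-over-post composition lands in the tunnel composites", {
  sp <- default_space()
  st <- compose_state(sp, "acute_stroke", "post_MI")
  expect_identical(st, "Non-fatal stroke + Post-MI")
  expect_true(sp$tunnel[sp$name == st])
  expect_identical(compose_state(sp, "acute_MI_2plus", "post_stroke_2plus"),
                   "Non-fatal MI 2+ + Post-stroke 2+")
})

test_that("transition matrix rows are stochastic and respect topology", {
  sp <- default_space()
  n <- nrow(sp)
  # no events, no mortality: tunnel states still advance to their chronic
  # successor; chronic states stay put
  M0 <- build_transition_matrix(sp, rep(0, n), rep(0, n), rep(0, n),
                                rep(0, n))
  expect_equal(unname(rowSums(M0)), rep(1, n), tolerance = 1e-14)
  i_post <- match("Post-MI", sp$name)
  expect_equal(M0[i_post, i_post], 1)
  expect_equal(M0["Non-fatal MI", "Post-MI"], 1)
  expect_equal(M0["Non-fatal stroke + Post-MI", "Post-MI + Post-stroke"], 1)
  # certain death: all living mass goes to the death states
  M1 <- build_transition_matrix(sp, rep(0, n), rep(0, n), rep(0.6, n),
                                rep(0.4, n))
  live <- !sp$absorbing
  expect_equal(unname(M1[live, "CV death"] + M1[live, "Non-CV death"]),
               rep(1, sum(live)))
  # random valid inputs: rows sum to one, acute states never self-loop,
  # death states only self-transition
  set.seed(101)
  for (rep_i in 1:25) {
    ip <- random_matrix_inputs(sp)
    M <- build_transition_matrix(sp, ip$p_mi, ip$p_stroke, ip$p_cv, ip$p_ncv)
    expect_true(all(abs(rowSums(M) - 1) <= 1e-12))
    expect_true(all(diag(M)[sp$tunnel] == 0))
    for (i in which(sp$absorbing)) {
      expect_equal(unname(M[i, i]), 1)
      expect_equal(sum(M[i, -i]), 0)
    }
    # a new event always routes through an acute tunnel state
    acute <- sp$phase %in% c("acute_MI", "acute_stroke")
    chronic_to_chronic <- M[!acute & !sp$absorbing,
                            !acute & !sp$absorbing, drop = FALSE]
    expect_true(all(chronic_to_chronic[upper.tri(chronic_to_chronic) |
                                         lower.tri(chronic_to_chronic)] == 0))
  }
})

test_that("invalid probabilities are rejected with the state named", {
  sp <- default_space()
  n <- nrow(sp)
  bad <- rep(0, n); bad[match("Post-MI", sp$name)] <- -0.01
  expect_error(build_transition_matrix(sp, bad, rep(0, n), rep(0, n),
                                       rep(0, n)), "Post-MI")
  expect_error(build_transition_matrix(sp, rep(1.5, n), rep(0, n),
                                       rep(0, n), rep(0, n)), "above 1")
})

test_that("death states are absorbing under reachability", {
  sp <- default_space()
  set.seed(7)
  ip <- random_matrix_inputs(sp)
  M <- build_transition_matrix(sp, ip$p_mi, ip$p_stroke, ip$p_cv, ip$p_ncv)
  # power up the chain: mass in death states never decreases
  v <- rep(1 / nrow(sp), nrow(sp))
  dead_prev <- sum(v[sp$absorbing])
  for (k in 1:30) {
    v <- as.numeric(v %*% M)
    dead <- sum(v[sp$absorbing])
    expect_gte(dead, dead_prev - 1e-12)
    dead_prev <- dead
  }
})

test_that("state space serializes to JSON with components and flags", {
  sp <- default_space()
  js <- jsonlite::fromJSON(state_space_json(sp), simplifyVector = FALSE)
  expect_length(js, nrow(sp))
  one <- js[[which(sp$name == "Non-fatal stroke + Post-MI")]]
  expect_true(one$tunnel)
  expect_setequal(unlist(one$components), c("acute_stroke", "post_MI"))
})

test_that("the minimal composite set drops the acute-over-post 2+ states", {
  sp_min <- build_state_space("minimal")
  sp <- default_space()
  expect_lt(nrow(sp_min), nrow(sp))
  expect_false("Non-fatal MI 2+ + Post-stroke" %in% sp_min$name)
  expect_true("Non-fatal MI + Post-stroke" %in% sp_min$name)
})
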