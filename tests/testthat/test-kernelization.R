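test_that("threshold recurrence has the claimed shape", {
  p <- kernel_params(k = 1, d = 2)
  expect_equal(p$B[2], 1)
  expect_equal(p$T[1], 1) # k * B(2)
  expect_equal(p$B[1], 2)
  p <- kernel_params(k = 4, d = 4)
  expect_equal(p$B, c(85, 21, 5, 1)) # B(j) = k * B(j+1) + 1
  expect_equal(p$B[1:3], p$T[1:3] + 1)
  expect_true(all(diff(p$B) < 0))
})

test_that("the basic reduction removes exactly the inert structure", {
  f1 <- make_triangle()
  iso <- hs_instance(c(f1$drugs, "v4"), unname(f1$classes), k = 2)
  red <- basic_reduce(iso)
  expect_false("v4" %in% red$instance$drugs)
  expect_true(same_instance(red$instance, f1))

  # beta = 0 class: members forbidden everywhere, then the class goes
  forb <- hs_instance(c("v1", "v2", "v3"), list(
    list(id = "b0", members = c("v1", "v2"), alpha = 0, beta = 0),
    list(id = "c2", members = c("v2", "v3"), alpha = 1)
  ), k = 2)
  red <- basic_reduce(forb)
  expect_equal(red$status, "ok")
  expect_identical(sort(red$instance$drugs), "v3")
  expect_identical(red$instance$classes[["c2"]]$members, "v3")
  # removing the forbidden drugs must not change the optimum of the alpha side
  expect_equal(brute_min_size(red$instance, 2)$size, 1)

  # drug only in zero-requirement unbounded classes is dropped
  lazy <- hs_instance(c("v1", "v2"), list(
    list(id = "z", members = c("v1", "v2"), alpha = 0),
    list(id = "c", members = "v1", alpha = 1)
  ), k = 1)
  expect_false("v2" %in% basic_reduce(lazy)$instance$drugs)

  # empty class demanding hits certifies a No-instance
  dead <- hs_instance("v1", list(list(id = "e", members = character(), alpha = 1)), k = 1)
  expect_equal(basic_reduce(dead)$status, "infeasible")
})

test_that("rule 1 forces tight classes and propagates bound decrements", {
  inst <- hs_instance(c("v1", "v2", "v3"), list(
    list(id = "c0", members = "v1", alpha = 1),
    list(id = "c1", members = c("v1", "v2"), alpha = 1),
    list(id = "c2", members = c("v2", "v3"), alpha = 1),
    list(id = "c3", members = c("v1", "v3"), alpha = 1)
  ), k = 2)
  red <- rule1_forced(inst)
  expect_identical(red$trace$forced, "v1")
  expect_equal(red$residual_k, 1)
  expect_equal(red$instance$classes[["c1"]]$alpha, 0)
  expect_equal(red$instance$classes[["c3"]]$alpha, 0)
  expect_equal(red$instance$classes[["c2"]]$alpha, 1)
  expect_false("c0" %in% names(red$instance$classes))

  # alpha equal to degree forces every member
  both <- hs_instance(c("v1", "v2"), list(
    list(id = "c", members = c("v1", "v2"), alpha = 2)
  ), k = 2)
  expect_setequal(rule1_forced(both)$trace$forced, c("v1", "v2"))

  # a forced pick that saturates a finite-beta class forbids its survivors
  sat <- hs_instance(c("v1", "v2", "v3"), list(
    list(id = "f", members = "v1", alpha = 1),
    list(id = "g", members = c("v1", "v2"), alpha = 0, beta = 1),
    list(id = "h", members = c("v2", "v3"), alpha = 1)
  ), k = 2)
  red <- rule1_forced(sat)
  expect_equal(red$status, "ok")
  expect_false("v2" %in% red$instance$drugs) # g saturated by v1, v2 forbidden

  # forcing into a class that cannot absorb the hit certifies No
  blocked <- hs_instance(c("v1", "v2"), list(
    list(id = "f", members = "v1", alpha = 1),
    list(id = "g", members = c("v1", "v2"), alpha = 1, beta = 1),
    list(id = "h", members = c("v1", "v2"), alpha = 2)
  ), k = 3)
  expect_equal(kernelize(blocked)$status, "infeasible")
})

test_that("rule 2 ignores only unconstrained satisfied classes", {
  f1 <- make_triangle()
  f1$classes[["c3"]]$alpha <- 0
  red <- rule2_satisfied(f1)
  expect_false("c3" %in% names(red$instance$classes))

  f1$classes[["c3"]]$beta <- 1 # upper bound still binds
  red <- rule2_satisfied(f1)
  expect_true("c3" %in% names(red$instance$classes))

  pristine <- make_triangle()
  expect_true(same_instance(rule2_satisfied(pristine)$instance, pristine))
})

test_that("rule 3 deletes dominated classes, respecting the beta guard", {
  sup <- hs_instance(c("v1", "v2", "v3"), list(
    list(id = "c1", members = c("v1", "v2"), alpha = 1),
    list(id = "c2", members = c("v1", "v2", "v3"), alpha = 1)
  ), k = 2)
  red <- rule3_dominated(sup)
  expect_identical(names(red$instance$classes), "c1")
  expect_equal(brute_min_size(red$instance, 2)$size, brute_min_size(sup, 2)$size)

  twin <- hs_instance(c("v1", "v2"), list(
    list(id = "c1", members = c("v1", "v2"), alpha = 1),
    list(id = "c2", members = c("v1", "v2"), alpha = 2)
  ), k = 2)
  red <- rule3_dominated(twin)
  expect_identical(names(red$instance$classes), "c2") # stricter twin wins
  expect_equal(brute_min_size(red$instance, 2)$size, brute_min_size(twin, 2)$size)

  dup <- hs_instance(c("v1", "v2"), list(
    list(id = "c2", members = c("v1", "v2"), alpha = 1),
    list(id = "c1", members = c("v2", "v1"), alpha = 1)
  ), k = 2)
  expect_identical(names(rule3_dominated(dup)$instance$classes), "c1")

  guarded <- hs_instance(c("v1", "v2", "v3"), list(
    list(id = "c1", members = c("v1", "v2"), alpha = 1),
    list(id = "c2", members = c("v1", "v2", "v3"), alpha = 1, beta = 2)
  ), k = 2)
  expect_length(rule3_dominated(guarded)$instance$classes, 2L)
})

test_that("the flower collapses to its core and the core is forced", {
  kern <- kernelize(make_flower(k = 1))
  expect_equal(kern$status, "ok")
  expect_identical(kern$trace$forced, "v0")
  expect_equal(kern$residual_k, 0)
  expect_length(kern$instance$classes, 0L)
  expect_length(kern$instance$drugs, 0L)
  types <- vapply(kern$trace$events, `[[`, character(1), "type")
  expect_true("class_replacement" %in% types)

  # a single petal stays below the threshold
  single <- hs_instance(c("v0", "w1"), list(
    list(id = "p1", members = c("v0", "w1"), alpha = 1)
  ), k = 1)
  types <- vapply(kernelize(single)$trace$events, `[[`, character(1), "type")
  expect_false("class_replacement" %in% types)

  # lifting the (empty) kernel solution recovers the forced core
  lifted <- lift_solution(check_feasible(kern$instance, character(), k = 0), kern)
  expect_identical(lifted$selected, "v0")
  expect_true(lifted$feasible)
  expect_equal(lifted$size, 1)
})

test_that("a shared 2-subset core is detected at level j = 2", {
  # four classes containing {v0, v1} with distinct third members; d = 3, k = 1
  # T(2) = k * B(3) = 1, so 4 > 1 triggers the replacement
  inst <- hs_instance(c("v0", "v1", "w1", "w2", "w3", "w4"), lapply(1:4, function(i) {
    list(id = paste0("c", i), members = c("v0", "v1", paste0("w", i)), alpha = 1)
  }), k = 1)
  red <- high_occurrence_reduce(inst)
  types <- vapply(red$trace$events, `[[`, character(1), "type")
  expect_true("class_replacement" %in% types)
  ev <- red$trace$events[[which(types == "class_replacement")[1]]]
  expect_setequal(ev$members, c("v0", "v1"))
  expect_length(ev$replaced, 4L)

  # answers agree with the oracle for every budget
  for (k in 0:3) {
    a <- brute_min_size(inst, k)$status
    kern <- kernelize(inst, k = k)
    b <- if (kern$status == "infeasible") {
      "infeasible"
    } else {
      brute_min_size(kern$instance, kern$residual_k)$status
    }
    expect_identical(a, b, info = paste("k =", k))
  }
})

test_that("kernelization preserves the answer and optimum on random instances", {
  for (s in 1:200) {
    inst <- suite_instance(s)
    orc <- brute_min_size(inst)
    kern <- kernelize(inst)
    if (kern$status == "infeasible") {
      expect_identical(orc$status, "infeasible", info = paste("seed", s))
      next
    }
    ko <- brute_min_size(kern$instance, k = kern$residual_k)
    if (ko$status == "infeasible") {
      expect_identical(orc$status, "infeasible", info = paste("seed", s))
      next
    }
    expect_identical(orc$status, "optimal", info = paste("seed", s))
    expect_equal(ko$size + length(kern$trace$forced), orc$size, info = paste("seed", s))
    lifted <- lift_solution(
      check_feasible(kern$instance, ko$selected, k = kern$residual_k), kern
    )
    expect_true(lifted$feasible, info = paste("seed", s))
    expect_equal(lifted$size, orc$size, info = paste("seed", s))
  }
})

test_that("kernelization is idempotent", {
  for (s in 1:60) {
    kern <- kernelize(suite_instance(s))
    if (kern$status == "infeasible") next
    again <- kernelize(kern$instance, k = kern$residual_k)
    expect_true(same_instance(again$instance, kern$instance), info = paste("seed", s))
    expect_equal(again$residual_k, kern$residual_k, info = paste("seed", s))
  }
})

test_that("the final verdict does not depend on the order rules 1-3 fire", {
  orders <- list(c(1L, 2L, 3L), c(3L, 2L, 1L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  verdict <- function(kern) {
    if (kern$status == "infeasible") {
      "no"
    } else if (brute_min_size(kern$instance, kern$residual_k)$status == "optimal") {
      "yes"
    } else {
      "no"
    }
  }
  for (s in 1:40) {
    inst <- suite_instance(s)
    vs <- vapply(orders, function(o) verdict(kernelize(inst, rule_order = o)), character(1))
    expect_length(unique(vs), 1L)
  }
})

test_that("traces replay: event counts match the reduction arithmetic", {
  for (s in 1:40) {
    kern <- kernelize(suite_instance(s))
    forced <- sum(vapply(kern$trace$events, function(e) e$type == "forced_drug", logical(1)))
    expect_equal(kern$trace$residual_k, kern$trace$original_k - forced)
    expect_length(kern$trace$forced, forced)
  }
})

test_that("zero budget with outstanding requirements is a No-instance", {
  kern <- kernelize(make_triangle(k = 0))
  expect_equal(kern$status, "infeasible")
})
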