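test_that("dichotomization thresholds at the frozen training mean, ties down", {
  expr <- matrix(c(1, 2, 3), 1, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(unname(dichotomize(expr, c(g1 = 2))[1, ]), c(0L, 0L, 1L))
  # constant gene equal to its mean: all down
  expr2 <- matrix(rep(5, 4), 1, dimnames = list("g1", paste0("s", 1:4)))
  expect_true(all(dichotomize(expr2, c(g1 = 5)) == 0L))
  expect_error(dichotomize(expr, c(other = 1)), "reference mean")
})

test_that("test cohorts are dichotomized with training means, not their own", {
  train <- matrix(rnorm(50, 5), 1, dimnames = list("g1", NULL))
  test <- train + 5                      # strongly shifted test cohort
  frozen <- rowMeans(train)
  st_frozen <- dichotomize(test, frozen)
  st_refit <- dichotomize(test, rowMeans(test))
  expect_true(all(st_frozen == 1L))      # everything above the frozen mean
  expect_false(all(st_refit == 1L))
})

test_that("contingency tables tally the joint states", {
  t1 <- pair_contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(t1[c("n11", "n10", "n01", "n00")], use.names = FALSE),
               c(1, 1, 1, 1))
  t2 <- pair_contingency(c(1, 0), c(1, 0))
  expect_equal(unlist(t2[c("n11", "n10", "n01", "n00")], use.names = FALSE),
               c(1, 0, 0, 1))
  set.seed(1)
  a <- rbinom(1000, 1, 0.5); b <- rbinom(1000, 1, 0.5)
  expect_equal(pair_contingency(a, b)$n, 1000)
  expect_error(pair_contingency(1, c(1, 0)), "length")
})

test_that("rule statistics match hand-computed prediction-logic values", {
  s <- rule_statistics(c(40, 10, 10, 40), "IMP")
  expect_equal(s$error_rate, 0.10)
  expect_equal(s$expected_error, 0.25)
  expect_equal(s$precision, 0.6)
  expect_equal(s$scope, 0.5)
  expect_equal(s$z_precision, 15 / sqrt(18.75), tolerance = 1e-12)
  expect_equal(s$p_precision, pnorm(3.4641016, lower.tail = FALSE),
               tolerance = 1e-6)

  s2 <- rule_statistics(c(45, 5, 5, 45), "EQV")
  expect_equal(s2$precision, 0.8)
  expect_equal(s2$z_precision, 8)
  expect_equal(s2$scope, 1)

  # exact independence: del 0, z 0, p 0.5 for every rule
  for (r in rule_types()) {
    s3 <- rule_statistics(c(25, 25, 25, 25), r)
    expect_equal(s3$precision, 0)
    expect_equal(s3$z_precision, 0)
    expect_equal(s3$p_precision, 0.5)
  }
})

test_that("degenerate margins and tiny expected error counts are flagged", {
  # all of A up: K = 0 for NOTIMP, rule undefined
  s <- rule_statistics(c(50, 50, 0, 0), "NOTIMP")
  expect_false(s$testable)
  expect_true(is.na(s$p_precision))
  # expected error count below the validity floor
  s2 <- rule_statistics(c(3, 0, 48, 49), "IMPNOT")   # N*K ~ 3*3/100
  expect_false(s2$testable)
})

test_that("a binding minimum-scope threshold can veto a narrow premise", {
  # premise covers 10/100 samples, far below the required 0.5
  s <- rule_statistics(c(8, 2, 45, 45), "IMP", min_scope = 0.5)
  expect_gt(s$p_scope, 0.99)
  st <- states_from_table(8, 2, 45, 45)
  expect_null(induce_relation(st$a, st$b, min_scope = 0.5))
})

test_that("equivalence statistics are symmetric in the gene order", {
  set.seed(42)
  for (i in 1:20) {
    tab <- random_dichotomized_table()
    for (r in c("EQV", "NEQV")) {
      s_ab <- rule_statistics(tab, r)
      s_ba <- rule_statistics(c(tab[1], tab[3], tab[2], tab[4]), r)
      expect_equal(s_ab$precision, s_ba$precision)
      expect_equal(s_ab$z_precision, s_ba$z_precision)
    }
  }
})

test_that("relabeling B to not-B maps each rule onto its complement", {
  set.seed(7)
  for (i in 1:20) {
    tab <- random_dichotomized_table()
    flipped <- c(tab[2], tab[1], tab[4], tab[3])   # B -> !B
    pairs <- list(c("IMP", "IMPNOT"), c("NOTIMP", "NOTIMPNOT"),
                  c("EQV", "NEQV"))
    for (p in pairs) {
      s1 <- rule_statistics(tab, p[1]); s2 <- rule_statistics(flipped, p[2])
      expect_equal(s1$error_rate, s2$error_rate)
      expect_equal(s1$expected_error, s2$expected_error)
      expect_equal(s1$precision, s2$precision)
    }
  }
})

test_that("perfect precision occurs exactly when the error cells are empty", {
  set.seed(11)
  for (i in 1:50) {
    tab <- random_dichotomized_table()
    r <- sample(rule_types(), 1)
    s <- rule_statistics(tab, r)
    if (is.na(s$precision) || s$expected_error == 0) next
    expect_equal(s$precision == 1, s$error_rate == 0)
  }
})

test_that("rule induction selects the maximum-precision significant rule", {
  st <- states_from_table(45, 5, 5, 45)
  sel <- induce_relation(st$a, st$b)
  expect_equal(sel$rule, "EQV")

  st2 <- states_from_table(25, 25, 25, 25)
  expect_null(induce_relation(st2$a, st2$b))

  # B = A OR noise: the directional rule is error-free (del = 1) and beats
  # the equivalence rule (del = 0.5)
  st3 <- states_from_table(50, 0, 25, 25)
  sel3 <- induce_relation(st3$a, st3$b)
  expect_equal(sel3$rule, "IMP")
  expect_equal(sel3$precision, 1)

  # degenerate vectors admit no rule
  expect_null(induce_relation(rep(1L, 50), rbinom(50, 1, 0.5)))
})

test_that("the selection policy is brute-force max-del among significant rules", {
  set.seed(13)
  for (i in 1:40) {
    tab <- random_dichotomized_table(c(40, 60))
    st <- states_from_table(tab[1], tab[2], tab[3], tab[4])
    sel <- induce_relation(st$a, st$b)
    all6 <- purrr::map_dfr(rule_types(), ~rule_statistics(tab, .x))
    sig <- all6[all6$testable & !is.na(all6$p_precision) &
                  all6$p_precision < 0.05 & all6$p_scope < 0.05 &
                  all6$precision > 0, ]
    if (nrow(sig) == 0) {
      expect_null(sel)
    } else {
      expect_equal(sel$precision, max(sig$precision))
    }
  }
})

test_that("z p-values agree with a Monte-Carlo draw from the test's null", {
  set.seed(19)
  n_fail <- 0; n_tab <- 0
  while (n_tab < 12) {
    tab <- random_dichotomized_table()
    rule <- rule_types()[(n_tab %% 6) + 1]
    s <- rule_statistics(tab, rule)
    if (!s$testable) next
    n_tab <- n_tab + 1
    p_emp <- mc_null_pvalue(tab, rule, n_draws = 4000)
    if (abs(p_emp - s$p_precision) > 0.05) n_fail <- n_fail + 1
  }
  expect_lte(n_fail, 1)
})

test_that("networks evaluate every unordered pair and find planted edges", {
  set.seed(5)
  # planted perfect equivalence pair among independent genes
  n <- 200
  a <- rbinom(n, 1, 0.5)
  states <- cbind(g1 = a, g2 = a, g3 = rbinom(n, 1, 0.5),
                  g4 = rbinom(n, 1, 0.5), g5 = rbinom(n, 1, 0.5))
  net <- build_network(states, alpha = 0.05)
  expect_s3_class(net, "implication_network")
  eq <- net$edges[net$edges$gene_a == "g1" & net$edges$gene_b == "g2", ]
  expect_equal(nrow(eq), 1)
  expect_equal(eq$rule, "EQV")
  expect_equal(eq$precision, 1)
  expect_identical(tidy(net), net$edges)

  # k genes -> k(k-1)/2 pairs: count via a fully planted clique
  b <- rbinom(50, 1, 0.5)
  clique <- matrix(b, 50, 4, dimnames = list(NULL, paste0("h", 1:4)))
  net2 <- build_network(clique)
  expect_equal(nrow(net2$edges), 4 * 3 / 2)
})

test_that("independent genes rarely produce edges", {
  set.seed(23)
  states <- matrix(rbinom(500 * 3, 1, 0.5), 500, 3,
                   dimnames = list(NULL, paste0("g", 1:3)))
  reps <- replicate(30, {
    s <- matrix(rbinom(300 * 3, 1, 0.5), 300, 3,
                dimnames = list(NULL, paste0("g", 1:3)))
    nrow(build_network(s)$edges)
  })
  expect_lt(mean(reps), 1)   # 3 pairs at ~10% per pair
})

test_that("the Pearson comparator flags exact and planted correlations", {
  set.seed(3)
  x <- rnorm(40)
  expr <- rbind(g1 = x, g2 = x, g3 = rnorm(40))
  net <- pearson_network(expr)
  hit <- net[net$gene_a == "g1" & net$gene_b == "g2", ]
  expect_equal(hit$r, 1)
  expect_equal(hit$sign, "+")

  # zero-variance gene is skipped, not an error
  expr2 <- rbind(expr, g4 = rep(1, 40))
  net2 <- pearson_network(expr2)
  expect_true("g4" %in% attr(net2, "skipped"))

  # a planted equivalence pair is seen by both network models
  st <- plant_rule_states("EQV", 150, violation_rate = 0.02, seed = 9)
  e <- rbind(gA = 5 + 1.5 * st$a + rnorm(150, 0, 0.3),
             gB = 6 + 1.5 * st$b + rnorm(150, 0, 0.3))
  imp <- build_network(cbind(gA = st$a, gB = st$b))
  pea <- pearson_network(e)
  expect_equal(nrow(imp$edges), 1)
  expect_equal(nrow(pea), 1)
})

test_that("null Pearson edges appear at roughly the nominal rate", {
  set.seed(29)
  expr <- matrix(rnorm(45 * 40), 45, 40,
                 dimnames = list(paste0("g", 1:45), NULL))
  net <- pearson_network(expr, alpha = 0.05)
  rate <- nrow(net) / choose(45, 2)
  expect_gt(rate, 0.01); expect_lt(rate, 0.10)
})
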