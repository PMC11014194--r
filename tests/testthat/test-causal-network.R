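test_that("trait discretization honours thresholds and boundary rules", {
  expect_identical(discretize_trait(0, c(-0.5, 0.5)), "Neutral")
  expect_identical(discretize_trait(-0.5, c(-0.5, 0.5)), "Restful") # boundary
  expect_identical(discretize_trait(0.5, c(-0.5, 0.5)), "Stressed") # boundary
  expect_error(discretize_trait(0, c(1, -1)), "increasing")

  # at +-1 sd of a standard-normal trait the state split is ~16/68/16
  set.seed(31)
  states <- discretize_trait(rnorm(1e4))
  freqs <- table(factor(states, c("Restful", "Neutral", "Stressed"))) / 1e4
  oracle <- c(pnorm(-1), pnorm(1) - pnorm(-1), pnorm(-1))
  expect_true(all(abs(as.numeric(freqs) - oracle) < 0.02))
})

test_that("network construction from a fit yields coherent CPTs", {
  spec <- default_path_spec()
  fit <- fit_path_model(simulate_subjects(spec, 2000, seed = 41), spec)
  net <- build_network(fit)
  # every CPT column sums to 1 (validated at construction; re-check directly)
  for (v in names(net$cpts)) {
    cpt <- net$cpts[[v]]
    sums <- if (length(net$parents[[v]]) == 0) sum(cpt) else
      apply(cpt, seq_along(dim(cpt))[-1], sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  expect_setequal(names(net$variables),
                  c("Age", "Sex", "Personality_trait", "Workload",
                    "GSR_marker", "HR_marker", "RR_marker", "Temp_marker"))

  # zero coefficients: trait CPT identical across parent configurations
  fit0 <- fit
  fit0$coefficients$estimate[] <- 0
  net0 <- build_network(fit0)
  pt0 <- net0$cpts$Personality_trait
  expect_true(all(abs(sweep(pt0, 1, pt0[, 1, 1]) ) < 1e-12))

  # flipping all trait coefficient signs reverses the P(Stressed) ordering
  fit_flip <- fit
  fit_flip$coefficients$estimate <- -fit_flip$coefficients$estimate
  ps <- as.numeric(build_network(fit)$cpts$Personality_trait["Stressed", , ])
  ps_flip <- as.numeric(build_network(fit_flip)$cpts$Personality_trait["Stressed", , ])
  expect_identical(order(ps), rev(order(ps_flip)))
})

test_that("inference matches the prior, degenerates under hard evidence", {
  net <- example_network()
  prior <- infer(net, query = "Sex")
  expect_equal(unname(prior$probabilities), c(0.5, 0.5), tolerance = 1e-12)
  post <- infer(net, evidence(hard = list(Workload = "Load")), "Workload")
  expect_equal(unname(post$probabilities[["Load"]]), 1)
  expect_error(infer(net, evidence(hard = list(Workload = "Busy")), "Workload"),
               "invalid state")
  expect_error(infer(net, query = "NoSuchNode"), "unknown query")
  # contradictory evidence: impossible joint configuration
  expect_error(
    infer(net, evidence(hard = list(Age = "30-39", Sex = "Male",
                                    Personality_trait = "Restful")),
          "Workload"),
    "inconsistent")
})

test_that("variable elimination equals full-joint enumeration on random nets", {
  for (k in 1:25) {
    net <- random_network(n_nodes = sample(3:8, 1), seed = 500 + k)
    ev <- random_evidence(net, seed = 700 + k)
    query <- sample(setdiff(names(net$variables),
                            c(names(ev$hard), names(ev$soft))), 1)
    got <- infer(net, ev, query)$probabilities
    want <- joint_posterior(net, ev, query)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("the scenario fixture reproduces the published prediction chain", {
  net <- example_network()
  demo <- evidence(hard = list(Age = "30-39", Sex = "Male"))
  r1 <- reasoning(net, "I", demo)
  expect_equal(unname(r1$posterior$probabilities),
               c(0.00, 0.82, 0.18), tolerance = 1e-9)
  expect_identical(r1$decision, "Neutral")
  expect_lt(r1$posterior$probabilities[["Restful"]], 0.005)

  # what-if: soft Stressed evidence raises P(Stressed) (tends to Stressed)
  ev2 <- evidence(hard = demo$hard,
                  soft = list(Personality_trait = trait_likelihood("Stressed")))
  r2 <- reasoning(net, "II", ev2)
  expect_gt(r2$posterior$probabilities[["Stressed"]],
            r1$posterior$probabilities[["Stressed"]])
  expect_equal(unname(r2$posterior$probabilities), c(0, 2 / 3, 1 / 3),
               tolerance = 1e-9)

  # sensors only (mode III), then all streams (composite)
  sens <- list(GSR_marker = c(Rest = 0.2, Load = 0.8),
               HR_marker = c(Rest = 0.25, Load = 0.75))
  r3 <- reasoning(net, "III", evidence(soft = sens))
  expect_gt(r3$posterior$probabilities[["Load"]], 0.5)
  rc <- reasoning(net, "composite",
                  evidence(hard = demo$hard,
                           soft = c(list(Personality_trait = trait_likelihood("Stressed")),
                                    sens)))
  expect_identical(rc$posterior$variable, "Workload")
  expect_gt(rc$posterior$probabilities[["Load"]],
            r3$posterior$probabilities[["Load"]] - 1) # completes coherently
  expect_error(reasoning(net, "I", evidence()), "needs hard Age and Sex")
  expect_error(reasoning(net, "III", demo), "sensor marker")
})

test_that("composite with uninformative sensors reduces to the trait-level chain", {
  net <- example_network()
  flat <- lapply(grep("_marker$", names(net$variables), value = TRUE),
                 function(v) c(Rest = 1, Load = 1))
  names(flat) <- grep("_marker$", names(net$variables), value = TRUE)
  ev_all <- evidence(hard = list(Age = "30-39", Sex = "Male"),
                     soft = c(list(Personality_trait = trait_likelihood("Stressed")),
                              flat))
  ev_noflat <- evidence(hard = list(Age = "30-39", Sex = "Male"),
                        soft = list(Personality_trait = trait_likelihood("Stressed")))
  comp <- reasoning(net, "composite", ev_all)$posterior$probabilities
  ref <- infer(net, ev_noflat, "Workload")$probabilities
  expect_equal(comp, ref, tolerance = 1e-9)
})

test_that("soft evidence favouring Load never lowers P(Workload = Load)", {
  net <- example_network()
  base_ev <- list(Age = "30-39", Sex = "Male")
  p_seq <- vapply(seq(0.05, 0.95, by = 0.1), function(l) {
    ev <- evidence(hard = base_ev,
                   soft = list(GSR_marker = c(Rest = 1 - l, Load = l)))
    infer(net, ev, "Workload")$probabilities[["Load"]]
  }, numeric(1))
  expect_true(all(diff(p_seq) > 0))
})

test_that("risk decisions apply the threshold as published", {
  mk_post <- function(p) structure(
    list(variable = "Workload",
         probabilities = c(Rest = 1 - p, Load = p), evidence = evidence()),
    class = "cw_posterior")
  d <- decide(mk_post(0.91), threshold = 0.8)
  expect_true(d$high_risk)
  expect_identical(d$label, "High CW Risk")
  expect_false(decide(mk_post(0.5), threshold = 0.8)$high_risk)
  expect_false(decide(mk_post(0.999), threshold = 1.0)$high_risk)
  expect_true(decide(mk_post(1.0), threshold = 1.0)$high_risk)
  bad <- structure(list(variable = "Personality_trait",
                        probabilities = c(Restful = 1, Neutral = 0, Stressed = 0)),
                   class = "cw_posterior")
  expect_error(decide(bad), "Workload")
})

test_that("network and evidence JSON round-trip at full precision", {
  net <- example_network()
  f <- tempfile(fileext = ".json")
  write_network(net, f)
  net2 <- read_network(f)
  expect_equal(net2$cpts, net$cpts, tolerance = 1e-12)
  expect_identical(net2$variables, net$variables)
  ev <- evidence(hard = list(Age = "30-39"),
                 soft = list(GSR_marker = c(Rest = 0.3, Load = 0.7)))
  fe <- tempfile(fileext = ".json")
  write_evidence(ev, fe)
  ev2 <- read_evidence(fe)
  expect_identical(ev2$hard$Age, "30-39")
  expect_equal(ev2$soft$GSR_marker, ev$soft$GSR_marker, tolerance = 1e-12)
  post1 <- infer(net, ev, "Workload")$probabilities
  post2 <- infer(net2, ev2, "Workload")$probabilities
  expect_equal(post1, post2, tolerance = 1e-12)
})

test_that("malformed networks and evidence are rejected", {
  vars <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  cpt_a <- array(c(0.5, 0.5), dim = 2, dimnames = list(A = vars$A))
  bad_b <- array(c(0.9, 0.3, 0.1, 0.7), dim = c(2, 2),
                 dimnames = list(B = vars$B, A = vars$A))
  expect_error(cw_network(vars, list(A = character(0), B = "A"),
                          list(A = cpt_a, B = bad_b)), "sum to 1")
  expect_error(evidence(hard = list(A = "a1"), soft = list(A = c(1, 0))),
               "both hard and soft")
  expect_error(evidence(soft = list(A = c(0, 0))), "not all zero")
})
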