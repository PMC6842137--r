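# The Boolean gene-selection language: parsing, set-level conditions,
# evaluation semantics (including the three-valued unevaluable policy).

demoSets <- function() {
  list(
    COMPULSORY_UPPER = speciesSet("COMPULSORY_UPPER",
                                  c("nmr", "human", "capuchin"), 3L),
    UPPER_GLIRES = speciesSet("UPPER_GLIRES", c("u1", "u2", "u3"), 1L),
    UPPER_PRIMATES = speciesSet("UPPER_PRIMATES", sprintf("p%d", 1:7), 2L),
    LOWER_GLIRES = speciesSet("LOWER_GLIRES", sprintf("l%d", 1:11), 2L),
    LOWER_PRIMATES = speciesSet("LOWER_PRIMATES", sprintf("q%d", 1:10),
                                2L),
    REFERENCE = speciesSet("REFERENCE", "mouse", 1L))
}

# a one-gene status matrix over the union of the sets' species
statusRow <- function(sets, present = character(), absent = character(),
                      unevaluable = character(), gene = "g") {
  species <- unique(unlist(lapply(sets, function(s) s@members)))
  st <- matrix("absent", 1, length(species),
               dimnames = list(gene, species))
  st[, ] <- "absent"
  st[1, present] <- "present"
  st[1, unevaluable] <- "unevaluable"
  st
}

test_that("the classic six-leaf screen predicate parses to an AND of six atoms", {
  sets <- demoSets()
  txt <- paste("absent_in(COMPULSORY_UPPER, 3) and absent_in(UPPER_GLIRES, 1)",
               "and absent_in(UPPER_PRIMATES, 2) and present_in(LOWER_GLIRES, 2)",
               "and present_in(LOWER_PRIMATES, 2) and present_in(REFERENCE, 1)")
  ast <- parsePredicate(txt, sets)
  expect_identical(ast$type, "and")
  expect_length(ast$children, 6L)
  ops <- vapply(ast$children, `[[`, "", "op")
  expect_identical(ops, c("absent", "absent", "absent", "present",
                          "present", "present"))
  ks <- vapply(ast$children, `[[`, 1L, "k")
  expect_identical(ks, c(3L, 1L, 2L, 2L, 2L, 1L))
  # keywords are case-insensitive; omitted k uses the set default
  ast2 <- parsePredicate("ABSENT_IN(UPPER_GLIRES) AND present_in(REFERENCE)",
                         sets)
  expect_identical(ast2$children[[1]]$k, 1L)
})

test_that("parse errors carry position and bad thresholds are rejected", {
  sets <- demoSets()
  expect_error(parsePredicate("present_in(NOSUCH, 1)", sets),
               "unknown species set 'NOSUCH'")
  expect_error(parsePredicate("present_in(UPPER_GLIRES, 9)", sets),
               "exceeds")
  expect_error(parsePredicate("present_in(UPPER_GLIRES", sets),
               "predicate syntax error")
  expect_error(parsePredicate("and and", sets), "line 1")
})

test_that("unparse(parse(t)) parses to an identical AST", {
  sets <- demoSets()
  txts <- c(
    "absent_in(UPPER_GLIRES, 1) and present_in(LOWER_GLIRES, 2)",
    "not (present_in(REFERENCE, 1) or absent_in(UPPER_PRIMATES, 3))",
    "not not present_in(REFERENCE, 1)",
    "(absent_in(UPPER_GLIRES, 1) or absent_in(UPPER_PRIMATES, 1)) and not present_in(LOWER_PRIMATES, 5)")
  for (t in txts) {
    ast <- parsePredicate(t, sets)
    expect_identical(parsePredicate(unparsePredicate(ast), sets), ast)
  }
})

test_that("set-level presence counts at-least-k member species", {
  sets <- demoSets()
  st <- statusRow(sets, present = c("l1", "l2"))
  expect_true(presentInSet("g", sets$LOWER_GLIRES, 2L, st))
  expect_false(presentInSet("g", sets$LOWER_GLIRES, 3L, st))
  expect_true(presentInSet("g", sets$LOWER_GLIRES, 0L, st))  # k = 0
  expect_false(presentInSet("g", sets$UPPER_GLIRES, 1L, st))
  expect_error(presentInSet("g", sets$LOWER_GLIRES, 2L,
                            st[, 1:3, drop = FALSE]),
               "missing presence call")
  expect_error(presentInSet("nope", sets$LOWER_GLIRES, 2L, st),
               "no presence calls")
})

test_that("set-level counting matches an explicit count on random matrices", {
  set.seed(31)
  sets <- list(S = speciesSet("S", sprintf("s%d", 1:10), 1L))
  for (i in 1:50) {
    st <- matrix(sample(c("present", "absent", "unevaluable"), 10, TRUE),
                 1, 10, dimnames = list("g", sprintf("s%d", 1:10)))
    k <- sample(0:10, 1)
    expect_identical(presentInSet("g", sets$S, k, st),
                     sum(st == "present") >= k)
    expect_identical(absentInSet("g", sets$S, k, st),
                     sum(st == "absent") >= k)
    # strict two-valued policy folds unevaluable into absent
    expect_identical(absentInSet("g", sets$S, k, st,
                                 strictTwoValued = TRUE),
                     sum(st != "present") >= k)
  }
})

test_that("unevaluable counts toward neither side under the default policy", {
  sets <- list(S = speciesSet("S", c("a", "b", "c"), 1L))
  st <- statusRow(sets, absent = c("a", "b"), unevaluable = "c")
  expect_false(absentInSet("g", sets$S, 3L, st))
  expect_true(absentInSet("g", sets$S, 3L, st, strictTwoValued = TRUE))
  expect_false(presentInSet("g", sets$S, 1L, st))
})

test_that("De Morgan: not present_in(S, 1) equals absent_in(S, |S|) on two-valued calls", {
  set.seed(57)
  sets <- list(S = speciesSet("S", sprintf("s%d", 1:6), 1L))
  lhs <- parsePredicate("not present_in(S, 1)", sets)
  rhs <- parsePredicate("absent_in(S, 6)", sets)
  for (i in 1:30) {
    st <- matrix(sample(c("present", "absent"), 6, TRUE), 1, 6,
                 dimnames = list("g", sprintf("s%d", 1:6)))
    expect_identical(evaluatePredicate("g", lhs, st, sets),
                     evaluatePredicate("g", rhs, st, sets))
  }
})

test_that("random predicates evaluate identically to a direct truth-table oracle", {
  set.seed(91)
  members <- sprintf("s%d", 1:8)
  sets <- list(A = speciesSet("A", members[1:4], 1L),
               B = speciesSet("B", members[3:8], 2L),
               C = speciesSet("C", members[c(1, 6)], 1L))
  randAST <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.4) {
      nm <- sample(names(sets), 1)
      return(list(type = "atom",
                  op = sample(c("present", "absent"), 1),
                  set = nm,
                  k = sample(0:length(sets[[nm]]@members), 1)))
    }
    typ <- sample(c("and", "or", "not"), 1)
    if (typ == "not") return(list(type = "not", child = randAST(depth - 1)))
    list(type = typ, children = lapply(seq_len(sample(2:3, 1)),
                                       function(i) randAST(depth - 1)))
  }
  # independent evaluator: build an R expression and eval() it
  oracleEval <- function(ast, st) {
    leaf <- function(node) {
      vals <- st[1, sets[[node$set]]@members]
      if (node$op == "present") sum(vals == "present") >= node$k
      else sum(vals == "absent") >= node$k
    }
    toExpr <- function(node) {
      switch(node$type,
        atom = as.character(leaf(node)),
        "not" = paste0("!(", toExpr(node$child), ")"),
        "and" = paste0("(", paste(vapply(node$children, toExpr, ""),
                                  collapse = " & "), ")"),
        "or" = paste0("(", paste(vapply(node$children, toExpr, ""),
                                 collapse = " | "), ")"))
    }
    eval(parse(text = toExpr(ast)))
  }
  for (i in 1:200) {
    ast <- randAST(3)
    st <- matrix(sample(c("present", "absent", "unevaluable"), 8, TRUE),
                 1, 8, dimnames = list("g", members))
    expect_identical(evaluatePredicate("g", ast, st, sets),
                     oracleEval(ast, st))
    # the predicate is pure: double negation never changes the verdict
    expect_identical(
      evaluatePredicate("g", list(type = "not",
                                  child = list(type = "not", child = ast)),
                        st, sets),
      evaluatePredicate("g", ast, st, sets))
  }
})

test_that("round-tripping random predicates through text preserves the AST", {
  set.seed(13)
  sets <- list(A = speciesSet("A", c("x", "y", "z"), 1L),
               B = speciesSet("B", c("u", "v"), 2L))
  randAST <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.5) {
      nm <- sample(names(sets), 1)
      return(list(type = "atom", op = sample(c("present", "absent"), 1),
                  set = nm,
                  k = sample(0:length(sets[[nm]]@members), 1)))
    }
    typ <- sample(c("and", "or", "not"), 1)
    if (typ == "not") return(list(type = "not", child = randAST(depth - 1)))
    list(type = typ,
         children = lapply(1:2, function(i) randAST(depth - 1)))
  }
  for (i in 1:50) {
    ast <- randAST(4)
    expect_identical(parsePredicate(unparsePredicate(ast), sets), ast)
  }
})
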