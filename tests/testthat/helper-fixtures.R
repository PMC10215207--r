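# Shared fixtures.  Everything is generated in code; heavyweight objects
# are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a small labeled phantom pair at the network grid
phantom_pair <- function(seed = 11, shape = c(32L, 32L, 32L)) {
  stack_case(generate_phantom(phantom_spec(shape = shape, seed = seed),
                              sprintf("fix%03d", seed)),
             shape)
}

# random BraTS-valued label volume
random_seg <- function(shape = c(8L, 8L, 8L), p3 = 0) {
  vals <- c(0, 1, 2, 4)
  probs <- c(0.7, 0.1, 0.1, 0.1)
  if (p3 > 0) { vals <- c(vals, 3); probs <- c(probs * (1 - p3), p3) }
  array(sample(vals, prod(shape), replace = TRUE, prob = probs), dim = shape)
}

# brute-force voxel-loop oracles (deliberately naive; independent of the
# vectorized implementations they check)
oracle_mask_counts <- function(seg) {
  wt <- tc <- et <- 0L
  for (v in as.vector(seg)) {
    if (v %in% c(1, 2, 4)) wt <- wt + 1L
    if (v %in% c(1, 4)) tc <- tc + 1L
    if (v == 4) et <- et + 1L
  }
  c(wt = wt, tc = tc, et = et)
}

oracle_dice <- function(a, b) {
  inter <- 0L; na <- 0L; nb <- 0L
  av <- as.vector(a); bv <- as.vector(b)
  for (i in seq_along(av)) {
    if (av[i] == 1) na <- na + 1L
    if (bv[i] == 1) nb <- nb + 1L
    if (av[i] == 1 && bv[i] == 1) inter <- inter + 1L
  }
  if (na + nb == 0L) return(1)
  2 * inter / (na + nb)
}

# closed-form parameter count for the whole architecture, written against
# the layer algebra only (independent of the builder's bookkeeping)
oracle_param_count <- function(in_ch, out_ch, depth, base, mult) {
  blk <- function(cin, cout) {
    (27 * cin + 1) * cout + (27 * cout + 1) * cout + 2 * (2 * cout)
  }
  ch <- c(base, base * mult^(0:(depth - 1)))
  total <- blk(in_ch, ch[1])
  for (i in seq_len(depth)) total <- total + blk(ch[i], ch[i + 1])
  for (j in depth:1) {
    ch_up <- if (j == depth) ch[depth + 1] else ch[j + 1]
    total <- total + blk(ch_up + ch[j], ch[j])
  }
  total + (ch[1] + 1) * out_ch
}

expect_nested <- function(masks) {
  m <- if (inherits(masks, "mask_stack")) masks$data else masks
  expect_true(all(m[3, , , ] <= m[2, , , ]))
  expect_true(all(m[2, , , ] <= m[1, , , ]))
}
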