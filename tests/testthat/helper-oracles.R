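# Independent reference implementations used as oracles. These are kept
# deliberately naive (scalar loops, explicit enumeration) and separate from
# the package's code paths.

ref_sigma <- function(x) 1 / (1 + exp(-x))

# Reference TD update for a fully specified episode trace: `fail` is the
# 1-based failing step, or 0 for a successful episode. Returns the updated
# q vector. Targets are computed in temporal order, mirroring an online
# learner that updates each visited state as its K-step window closes.
ref_td_update <- function(q, alpha, k, fail, reward, K = 1) {
  last_correct <- if (fail == 0) k else fail - 1
  if (last_correct >= 1 && alpha > 0) {
    for (i in seq_len(last_correct)) {
      target <- if (fail == 0) {
        if (i + K > k) reward else q[i + K]
      } else {
        if (i + K <= fail) q[i + K] else 0
      }
      q[i] <- q[i] + alpha * (target - q[i])
    }
  }
  q
}

# Closed-form EMA of a constant stream folded into s.
ref_ema_block <- function(s, x, beta) {
  for (xi in x) s <- (1 - beta) * s + beta * xi
  s
}

# Exhaustive two-decision expectimax for a tiny curriculum POMDP with a
# point-mass belief. Enumerates every ordered episode trace (success, or
# failure at step j) of the T-episode block, updates the student and the
# tracker exactly, groups traces by the observable success count for the
# second decision (the information the planner branches on), and returns
# the optimal first move. Used to check pomcp_search.
expectimax_root <- function(q, eps_vec, alpha, level, shat, spec, gamma,
                            reward) {
  moves <- c("DECREMENT", "STAY", "INCREMENT")
  N <- spec$n_levels
  clamp <- function(lev, mv) switch(mv, DECREMENT = max(lev - 1, 1),
                                    STAY = lev, INCREMENT = min(lev + 1, N))

  # enumerate all trace sequences of one block at level k:
  # returns list of (prob, q', outcomes vector)
  enum_block <- function(q, k, T_att) {
    res <- list(list(p = 1, q = q, out = integer(0)))
    for (t in seq_len(T_att)) {
      nxt <- list()
      for (br in res) {
        ps <- ref_sigma(br$q[seq_len(k)] + eps_vec[seq_len(k)])
        # success
        p_s <- prod(ps)
        nxt[[length(nxt) + 1]] <- list(
          p = br$p * p_s,
          q = ref_td_update(br$q, alpha, k, 0, reward),
          out = c(br$out, 1L)
        )
        # failure at step j
        cum <- 1
        for (j in seq_len(k)) {
          pf <- cum * (1 - ps[j])
          nxt[[length(nxt) + 1]] <- list(
            p = br$p * pf,
            q = ref_td_update(br$q, alpha, k, j, reward),
            out = c(br$out, 0L)
          )
          cum <- cum * ps[j]
        }
      }
      res <- nxt
    }
    res
  }

  q_move2 <- function(q, lev, shat) {
    # one-step lookahead value of the best second move (no continuation
    # beyond the planning horizon)
    vals <- vapply(moves, function(mv) {
      k <- clamp(lev, mv)
      brs <- enum_block(q, k, spec$T_attempts)
      sum(vapply(brs, function(br) {
        s2 <- shat
        s2[k] <- ref_ema_block(s2[k], br$out, spec$beta)
        r <- as.numeric(k == N && s2[N] >= spec$tau)
        br$p * r
      }, numeric(1)))
    }, numeric(1))
    max(vals)
  }

  root_vals <- vapply(moves, function(mv) {
    k <- clamp(level, mv)
    brs <- enum_block(q, k, spec$T_attempts)
    # group non-terminal continuations by observable success count
    key <- vapply(brs, function(br) sum(br$out), numeric(1))
    total <- 0
    for (o in unique(key)) {
      grp <- brs[key == o]
      for (br in grp) {
        s2 <- shat
        s2[k] <- ref_ema_block(s2[k], br$out, spec$beta)
        br$s2 <- s2
      }
      # immediate rewards are trace-exact
      rs <- vapply(grp, function(br) {
        s2 <- shat
        s2[k] <- ref_ema_block(s2[k], br$out, spec$beta)
        as.numeric(k == N && s2[N] >= spec$tau)
      }, numeric(1))
      ps <- vapply(grp, `[[`, numeric(1), "p")
      total <- total + sum(ps * rs)
      # optimal second move is chosen per observation branch, against the
      # branch-conditional mixture of surviving (non-terminal) traces
      alive <- rs < 1
      if (any(alive)) {
        cont_by_move <- vapply(moves, function(mv2) {
          sum(vapply(which(alive), function(ix) {
            br <- grp[[ix]]
            s2 <- shat
            s2[k] <- ref_ema_block(s2[k], br$out, spec$beta)
            k2 <- clamp(k, mv2)
            brs2 <- enum_block(br$q, k2, spec$T_attempts)
            br$p * sum(vapply(brs2, function(b2) {
              s3 <- s2
              s3[k2] <- ref_ema_block(s3[k2], b2$out, spec$beta)
              b2$p * as.numeric(k2 == N && s3[N] >= spec$tau)
            }, numeric(1)))
          }, numeric(1)))
        }, numeric(1))
        total <- total + gamma * max(cont_by_move)
      }
    }
    total
  }, numeric(1))
  list(action = moves[which.max(root_vals)], values = root_vals)
}

# The set of post-move levels achieving the oracle's optimal value. With
# moves clamped at the ends of the level range, distinct move labels can
# denote the same effective action (STAY vs INCREMENT at the top level),
# and exact value ties are common; agreement is judged on resulting
# levels.
expectimax_best_levels <- function(values, level, n_levels, tol = 1e-9) {
  moves <- c("DECREMENT", "STAY", "INCREMENT")
  lev <- vapply(moves, function(mv) switch(mv,
    DECREMENT = max(level - 1, 1), STAY = level,
    INCREMENT = min(level + 1, n_levels)), numeric(1))
  unique(lev[values >= max(values) - tol])
}

move_level <- function(move, level, n_levels) {
  switch(move, DECREMENT = max(level - 1, 1), STAY = level,
         INCREMENT = min(level + 1, n_levels))
}
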