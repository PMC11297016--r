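# Independent pure-R geometric oracle for the turning rule.  Works
# directly from the model definition on explicit position lists, with no
# shared code with the package engine; used to cross-check applicability,
# successor configurations and reachability on small machines.

ORC_DIRS <- matrix(c(1, 0,  0, 1,  -1, 1,  -1, 0,  0, -1,  1, -1),
                   ncol = 2, byrow = TRUE)

orc_positions <- function(states0, moves) {
  n <- length(states0)
  sgn <- sign(states0)
  dirs <- (sgn * moves) %% 6  # east-line initial geometry
  pos <- matrix(0L, n, 2)
  for (i in seq_len(n - 1)) {
    pos[i + 1, ] <- pos[i, ] + ORC_DIRS[dirs[i] + 1, ]
  }
  pos
}

orc_simple <- function(pos) !anyDuplicated(paste(pos[, 1], pos[, 2]))

# applicability by literal head-translation overlap test
orc_applicable <- function(states0, moves, i) {
  n <- length(states0)
  s <- states0[i] - sign(states0[i]) * moves[i]
  if (s == 0) return(FALSE)
  if (i == n) return(TRUE)
  pos <- orc_positions(states0, moves)
  diri <- (sign(states0[i]) * moves[i]) %% 6
  i2 <- (diri + if (s > 0) 2 else -2) %% 6
  d <- ORC_DIRS[i2 + 1, ]
  head_shifted <- sweep(pos[(i + 1):n, , drop = FALSE], 2, -d)
  tail_keys <- paste(pos[1:i, 1], pos[1:i, 2])
  !any(paste(head_shifted[, 1], head_shifted[, 2]) %in% tail_keys)
}

orc_applicable_set <- function(states0, moves) {
  Filter(function(i) orc_applicable(states0, moves, i),
         seq_along(states0))
}

# exhaustive reachable move-count vectors by BFS, oracle-only
orc_explore <- function(states0) {
  n <- length(states0)
  start <- integer(n)
  seen <- new.env(hash = TRUE)
  key <- function(mv) paste(mv, collapse = ",")
  seen[[key(start)]] <- TRUE
  queue <- list(start)
  out <- list(start)
  while (length(queue)) {
    mv <- queue[[1]]
    queue <- queue[-1]
    for (i in orc_applicable_set(states0, mv)) {
      mv2 <- mv
      mv2[i] <- mv2[i] + 1L
      k <- key(mv2)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        queue[[length(queue) + 1]] <- mv2
        out[[length(out) + 1]] <- mv2
      }
    }
  }
  do.call(rbind, out)
}

# random small programs for the dual-route equivalence checks
random_program <- function(n, smax, seed) {
  set.seed(seed)
  states <- sample(seq(-smax, smax), n, replace = TRUE)
  tm_program(c(states[-n], 0L), name = sprintf("rand(%d,%d)", n, seed))
}

# random positive zig-zag path of the given length starting at the origin
random_zigzag <- function(len, seed) {
  set.seed(seed)
  pos <- matrix(0L, len, 2)
  keys <- "0 0"
  for (i in seq_len(len - 1)) {
    repeat {
      d <- ORC_DIRS[sample(c(1, 2, 3, 4), 1), ]  # +x, +y, +w, -x
      nxt <- pos[i, ] + d
      if (!(paste(nxt[1], nxt[2]) %in% keys)) break
    }
    pos[i + 1, ] <- nxt
    keys <- c(keys, paste(nxt[1], nxt[2]))
  }
  pos
}
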