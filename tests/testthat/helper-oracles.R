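# Independent pure-R oracles. These re-implement the contracts (pinned
# scoring: match +1, mismatch -1, gap -1 linear; tie-break diagonal > up >
# left) without touching the package's C++ path.

oracle_align <- function(a, b, local = FALSE) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  n1 <- length(a); n2 <- length(b)
  S <- matrix(0L, n1 + 1, n2 + 1)
  M <- matrix(0L, n1 + 1, n2 + 1)
  C <- matrix(0L, n1 + 1, n2 + 1)
  if (!local) {
    S[1, ] <- -(0:n2); C[1, ] <- 0:n2
    S[, 1] <- -(0:n1); C[, 1] <- 0:n1
  }
  best <- c(score = 0L, matches = 0L, columns = 0L)
  for (i in 2:(n1 + 1)) {
    if (!local) { S[i, 1] <- -(i - 1L); C[i, 1] <- i - 1L }
    for (j in 2:(n2 + 1)) {
      eq <- a[i - 1] == b[j - 1]
      sd <- S[i - 1, j - 1] + if (eq) 1L else -1L
      su <- S[i - 1, j] - 1L
      sl <- S[i, j - 1] - 1L
      if (sd >= su && sd >= sl) {
        s <- sd; m <- M[i - 1, j - 1] + as.integer(eq); cc <- C[i - 1, j - 1] + 1L
      } else if (su >= sl) {
        s <- su; m <- M[i - 1, j]; cc <- C[i - 1, j] + 1L
      } else {
        s <- sl; m <- M[i, j - 1]; cc <- C[i, j - 1] + 1L
      }
      if (local && s <= 0L) { s <- 0L; m <- 0L; cc <- 0L }
      S[i, j] <- s; M[i, j] <- m; C[i, j] <- cc
      if (local && s > best["score"]) {
        best <- c(score = s, matches = m, columns = cc)
      }
    }
  }
  if (!local) {
    best <- c(score = S[n1 + 1, n2 + 1], matches = M[n1 + 1, n2 + 1],
              columns = C[n1 + 1, n2 + 1])
  }
  best
}

oracle_identity_global <- function(a, b) {
  st <- oracle_align(a, b, local = FALSE)
  unname(st["matches"]) / min(nchar(a), nchar(b))
}

# greedy incremental clustering, independently coded
oracle_greedy_cluster <- function(ids, seqs, threshold) {
  ord <- order(-nchar(seqs), ids)
  rep_seq <- character(0); rep_id <- character(0)
  assign <- setNames(integer(length(ids)), ids)
  for (i in ord) {
    placed <- 0L
    for (cl in seq_along(rep_seq)) {
      if (oracle_identity_global(seqs[i], rep_seq[cl]) >= threshold) {
        placed <- cl
        break
      }
    }
    if (placed == 0L) {
      rep_seq <- c(rep_seq, seqs[i]); rep_id <- c(rep_id, ids[i])
      placed <- length(rep_seq)
    }
    assign[ids[i]] <- placed
  }
  list(assign = assign, rep_id = rep_id)
}

rand_dna <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_dna <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
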