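# Brute-force split-plot sums of squares from cell/marginal means, written
# independently of the implementation (the oracle for the mixed ANOVA).
ss_oracle <- function(tab) {
  gm <- mean(tab$value)
  subj_means <- tapply(tab$value, tab$subject_id, mean)
  subj_group <- tapply(tab$group, tab$subject_id, function(g) g[1])
  group_means <- tapply(tab$value, tab$group, mean)
  time_means <- tapply(tab$value, tab$time, mean)
  cell_means <- tapply(tab$value, list(tab$group, tab$time), mean)
  n_time <- length(unique(tab$time))
  n_per_group <- table(subj_group)

  ss_group <- sum(n_per_group[names(group_means)] * n_time *
                    (group_means - gm)^2)
  ss_subj <- n_time * sum((subj_means - group_means[subj_group])^2)
  ss_time <- sum(table(tab$time)[names(time_means)] * (time_means - gm)^2)
  ss_int <- 0
  for (g in rownames(cell_means)) for (t in colnames(cell_means)) {
    ss_int <- ss_int + n_per_group[g] *
      (cell_means[g, t] - group_means[g] - time_means[t] + gm)^2
  }
  ss_tot <- sum((tab$value - gm)^2)
  ss_err_within <- ss_tot - ss_group - ss_subj - ss_time - ss_int
  c(group = unname(ss_group), subj = unname(ss_subj), time = unname(ss_time),
    int = unname(ss_int), err = unname(ss_err_within), total = ss_tot)
}

make_mixed_table <- function(values_by_subject, groups) {
  n <- length(values_by_subject)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = sprintf("s%02d", i), group = groups[i],
               time = c("t1", "t2"), value = values_by_subject[[i]])
  }))
}
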