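# Shared fixtures: all built in code, no files.

TT <- as.POSIXct("2023-02-01 12:00:00", tz = "UTC")

normal_vitals <- function(trigger = TT) {
  vital_samples(rep(trigger - 3600, 5),
                c("HR", "RR", "SBP", "TEMP", "SPO2"),
                c(80, 16, 120, 37, 98))
}

# a valid adult snapshot with normal findings; override any field
make_snapshot <- function(patient_id = "P1", age_years = 50,
                          sex_assigned_at_birth = "female",
                          administrative_sex = "female",
                          vitals = normal_vitals(trigger),
                          gcs = data.frame(time = trigger - 1800, value = 15L),
                          trigger = TT, ...) {
  patient_snapshot(patient_id = patient_id, age_years = age_years,
                   sex_assigned_at_birth = sex_assigned_at_birth,
                   administrative_sex = administrative_sex,
                   vitals = vitals, gcs = gcs, trigger_time = trigger, ...)
}

# 5-concept toy is-a graph: two cancers under a root (one of them a skin
# cancer used for exclusion tests), one heart-failure subtype
toy_graph <- function(exclusions = list()) {
  concept_graph(
    edges = data.frame(
      child = c("skin_ca", "bcc", "lung_ca", "chf", "copd"),
      parent = c("ca_root", "skin_ca", "ca_root", "hf_root", "cld_root")),
    category_roots = list(cancer = "ca_root", heart_failure = "hf_root",
                          chronic_lung_disease = "cld_root"),
    exclusions = exclusions)
}

# random DAG over n nodes: edges only from lower to higher index, so
# acyclicity holds by construction
random_dag <- function(n, p_edge = 0.08) {
  from <- character(0); to <- character(0)
  ids <- sprintf("n%03d", seq_len(n))
  for (i in seq_len(n - 1)) {
    js <- which(runif(n - i) < p_edge) + i
    from <- c(from, rep(ids[i], length(js)))
    to <- c(to, ids[js])
  }
  if (!length(from)) { from <- ids[1]; to <- ids[2] }
  data.frame(child = from, parent = to)
}

# breadth-first reachability oracle, independent of the package's memoized
# closure
bfs_ancestors <- function(code, edges) {
  frontier <- edges$parent[edges$child == code]
  seen <- character(0)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(edges$parent[edges$child %in% frontier]), seen)
  }
  seen
}
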