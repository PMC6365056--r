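# shared fixtures: small synthetic trial tables built in code

# boundary separation 0.8 calibrated against the reference median SDT counts
# for a single subject without trial-level drift variability (conservative
# H ~ .71 / FA ~ .014, liberal H ~ .84 / FA ~ .20)
ref_liberal <- function(a = 0.8, t_nd = 0.28)
  ddm_params(v = 2.39, a = a, z_frac = 0.24, db = 2.08, t_nd = t_nd)

ref_conservative <- function(a = 0.8, t_nd = 0.32)
  ddm_params(v = 3.06, a = a, z_frac = 0.24, db = -0.04, t_nd = t_nd)

# simulate one condition's trial block (targets + nontargets)
sim_condition <- function(params, cond, n_target, n_nontarget, seed,
                          dt = 1e-3, deadline = 0.84) {
  tg <- ddm_simulate(params, "target", n_target, dt = dt,
                     deadline = deadline, seed = seed)
  ng <- ddm_simulate(params, "nontarget", n_nontarget, dt = dt,
                     deadline = deadline, seed = seed + 1L)
  rbind(data.frame(condition = cond, stimulus = "target", tg),
        data.frame(condition = cond, stimulus = "nontarget", ng))
}

# two-condition table at roughly the study's per-condition trial counts
sim_two_condition <- function(seed, n_lib = c(1080L, 360L),
                              n_con = c(1440L, 480L),
                              lib = ref_liberal(),
                              con = ref_conservative()) {
  rbind(sim_condition(lib, "liberal", n_lib[1], n_lib[2], seed),
        sim_condition(con, "conservative", n_con[1], n_con[2], seed + 100L))
}

# trial table from SDT category counts (choices only, no RTs needed)
sdt_count_table <- function(hits, misses, fas, crs) {
  data.frame(
    subject = 1L, condition = "x",
    stimulus = rep(c("target", "nontarget"), c(hits + misses, fas + crs)),
    choice = c(rep(c("press", "none"), c(hits, misses)),
               rep(c("press", "none"), c(fas, crs))))
}
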