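# Default functional-group parameterisation for the six Central Anatolian
# steppe growth forms.
#
# Schema (one block per group under `groups:`):
#   maxab        max within-cell abundance class (1..3; 1 caps continuous
#                per-cell group abundance at 1.0 under the package's reading)
#   mature_age   age (years) at first seed/shoot production
#   max_age      lifespan (years)
#   size         height of immatures relative to matures (1..4; 4 = same)
#   stratum      [immature, mature] canopy layer, 1 (ground) .. 5 (high canopy)
#   dispersal    s_rate/m_rate/h_rate: short/medium/long band capacity
#                (levels 0 No, 1 Low, 2 Med, 3 High); k_disp: two decay
#                constants of the long-distance tail; limits: short/medium/
#                long band extents in meters
#   fecundity    seeds released per cell with mature plants per year
#   germination  germination level (0..4) under low/medium/high resource
#   survival     germinant/immature/mature survival (boolean) under
#                low/medium/high resource
#   disturbance  age_breakpoints: right-open age-class bounds;
#                kill/resprout/respage: per age class, cohort fraction killed
#                (level 0..4), fraction resprouting (level 0..4) and the age
#                resprouted shoots restart at (-1 = no resprouting);
#                seed_broken: emergence stimulation after the event;
#                propkill: fraction of propagules destroyed by the event
groups:
  non_spiny_subshrub:
    label: "non-spiny subshrub"
    maxab: 1
    mature_age: 2
    max_age: 30
    size: 1
    stratum: [1, 2]
    dispersal: {s_rate: high, m_rate: low, h_rate: low, k_disp: [2, 10], limits: [5, 10, 50]}
    fecundity: 3
    germination: {low: 0, medium: 1, high: 2}
    survival:
      germinant: [no, no, yes]
      immature: [no, yes, yes]
      mature: [yes, yes, yes]
    disturbance:
      age_breakpoints: [2, 5]
      seed_broken: 0
      propkill: 0
      kill: [3, 3, 1]
      resprout: [0, 1, 2]
      respage: [0, 1, 2]
  spiny_subshrub:
    label: "spiny subshrub"
    maxab: 1
    mature_age: 2
    max_age: 30
    size: 1
    stratum: [1, 2]
    dispersal: {s_rate: high, m_rate: low, h_rate: low, k_disp: [2, 10], limits: [5, 10, 50]}
    fecundity: 3
    germination: {low: 0, medium: 1, high: 2}
    survival:
      germinant: [no, no, yes]
      immature: [no, yes, yes]
      mature: [yes, yes, yes]
    disturbance:
      age_breakpoints: [2, 5]
      seed_broken: 0
      propkill: 0
      kill: [3, 2, 0]
      resprout: [0, 1, 1]
      respage: [0, 1, 2]
  perennial_forb:
    label: "perennial forb"
    maxab: 1
    mature_age: 1
    max_age: 5
    size: 2
    stratum: [1, 1]
    dispersal: {s_rate: high, m_rate: med, h_rate: low, k_disp: [3, 20], limits: [5, 30, 100]}
    fecundity: 3
    germination: {low: 1, medium: 1, high: 1}
    survival:
      germinant: [no, yes, yes]
      immature: [yes, yes, yes]
      mature: [yes, yes, yes]
    disturbance:
      age_breakpoints: [2]
      seed_broken: 0
      propkill: 0
      kill: [3, 1]
      resprout: [0, 2]
      respage: [1, 2]
  perennial_gramineae:
    label: "perennial gramineae"
    maxab: 1
    mature_age: 2
    max_age: 5
    size: 2
    stratum: [1, 1]
    dispersal: {s_rate: high, m_rate: low, h_rate: low, k_disp: [3, 10], limits: [5, 10, 50]}
    fecundity: 3
    germination: {low: 1, medium: 1, high: 1}
    survival:
      germinant: [no, yes, yes]
      immature: [yes, yes, yes]
      mature: [yes, yes, yes]
    disturbance:
      age_breakpoints: [1]
      seed_broken: 0
      propkill: 0
      kill: [3, 0]
      resprout: [0, 3]
      respage: [1, 2]
  annual:
    label: "annual herb"
    maxab: 1
    mature_age: 1
    max_age: 2
    size: 4
    stratum: [1, 1]
    dispersal: {s_rate: high, m_rate: low, h_rate: "no", k_disp: [2, 10], limits: [5, 10, 20]}
    fecundity: 5
    germination: {low: 1, medium: 1, high: 1}
    survival:
      germinant: [no, no, yes]
      immature: [no, no, yes]
      mature: [no, yes, yes]
    disturbance:
      age_breakpoints: [1]
      seed_broken: 0
      propkill: 0
      kill: [1, 3]
      resprout: [0, 0]
      respage: [-1, -1]
  resprouter_tree:
    label: "resprouter tree"
    maxab: 1
    mature_age: 10
    max_age: 300
    size: 1
    stratum: [1, 3]
    dispersal: {s_rate: high, m_rate: high, h_rate: high, k_disp: [2, 10], limits: [10, 50, 100]}
    fecundity: 2
    germination: {low: 1, medium: 2, high: 3}
    survival:
      germinant: [no, yes, yes]
      immature: [yes, yes, yes]
      mature: [yes, yes, yes]
    disturbance:
      age_breakpoints: [3, 10]
      seed_broken: 0
      propkill: 0
      kill: [3, 2, 0]
      resprout: [0, 1, 0]
      respage: [1, 5, 10]
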