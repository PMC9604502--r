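# shared fixtures built in code

# HeLa-like parameter set derived from first principles; frozen reference
# numbers for it live in the tests that use them
hela_params <- function() bundled_cell_lines("HeLa")$HeLa

# printed reference values for the 14 bundled parameter sets:
# photon alpha/beta, nucleus radius (1 d.p.) and domain radius (2 d.p.)
table2_printed <- function() {
  read.csv(text = "key,alpha_ref,beta_ref,Rn,rd,Rn_derived
C3H10T1_2,0.173,0.0389,4.0,0.26,FALSE
CHO,0.226,0.0231,4.2,0.27,FALSE
HeLa,0.536,0.0278,5.6,0.29,FALSE
HF19,0.557,0.0189,4.7,0.29,TRUE
HL60,0.315,0.0558,4.6,0.29,TRUE
M10,0.3,0.068,4.7,0.29,TRUE
NB1RGB,0.476,0.0458,5.1,0.32,FALSE
PDV,0.13,0.037,5.1,0.29,TRUE
RAT1,0.201,0.0266,5.0,0.29,TRUE
SQ20B,0.122,0.0238,4.5,0.30,TRUE
T1,0.159,0.0391,4.7,0.29,TRUE
TK1,0.107,0.0384,4.7,0.29,TRUE
U87,0.106,0.0557,4.5,0.30,TRUE
U251MG,0.031,0.0551,4.9,0.29,TRUE", stringsAsFactors = FALSE)
}

# round-half-up at d decimals (printed-table convention)
round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d

# tiny log-uniform grid whose bin representatives are exactly 1, 3, 9
grid_rep_139 <- function()
  le_grid(ymin = 3^-0.5, ymax = 3^2.5, bins_per_decade = 3 / log10(3^3))
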