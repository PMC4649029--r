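# Fixture builders shared across the suite. Everything is generated in code;
# no stored data.

# inflow/decay model with positive steady state k0/a (scalar OU around it)
ou_model <- function(k0 = 10, a = 1) {
  kinetic_model("S", matrix(c(1, -1), 1, 2),
                list(quote(k0), quote(a * S)),
                c(k0 = k0, a = a), initial_state = c(S = k0 / a))
}

# pure exponential decay dS/dt = -a S (steady state at 0; linear toy)
decay_model <- function(a = 1) {
  kinetic_model("S", matrix(-1, 1, 1), list(quote(a * S)), c(a = a),
                initial_state = c(S = 1))
}

# irreversible chain A -> B, single mass-action reaction v = k1 * A
chain_ab <- function(k1 = 2, reversible = FALSE) {
  kinetic_model(c("A", "B"), matrix(c(-1, 1), 2, 1),
                list(quote(k1 * A)), c(k1 = k1),
                reversible = reversible, initial_state = c(A = 3, B = 0))
}

# chain A -> B -> (out), two mass-action steps
chain_abo <- function(k1 = 2, k2 = 0.7) {
  kinetic_model(c("A", "B"), matrix(c(-1, 1, 0, -1), 2, 2),
                list(quote(k1 * A), quote(k2 * B)), c(k1 = k1, k2 = k2),
                initial_state = c(A = 3, B = 0))
}

# two-species stable linear model with inflow: dA = kin - k1 A, dB = k1 A - k2 B
linear2_model <- function(kin = 2, k1 = 1, k2 = 0.5) {
  kinetic_model(c("A", "B"), matrix(c(1, 0, -1, 1, 0, -1), 2, 3),
                list(quote(kin), quote(k1 * A), quote(k2 * B)),
                c(kin = kin, k1 = k1, k2 = k2), initial_state = c(A = 2, B = 4))
}

# random Hurwitz-stable dense J and PSD D, independent of any kinetic model
stable_JD <- function(n, seed) {
  set.seed(seed)
  J <- matrix(stats::rnorm(n * n), n, n)
  diag(J) <- diag(J) - n
  G <- matrix(stats::rnorm(n * n), n, n)
  list(J = J, D = crossprod(G) / n)
}

# Kronecker brute-force solve of J C + C J^T = -2 D (test oracle only)
kron_lyap <- function(J, D) {
  n <- nrow(J)
  K <- diag(n) %x% J + J %x% diag(n)
  matrix(solve(K, as.vector(-2 * D)), n, n)
}

# minimal SBML document text; species B fixed as a boundary pool
minimal_sbml <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">
  <model id="decay1">
    <listOfCompartments><compartment id="cell" size="1"/></listOfCompartments>
    <listOfSpecies>
      <species id="A" compartment="cell" initialConcentration="2"/>
    </listOfSpecies>
    <listOfParameters><parameter id="k" value="0.5"/></listOfParameters>
    <listOfReactions>
      <reaction id="deg" reversible="false">
        <listOfReactants><speciesReference species="A"/></listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k</ci><ci>A</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}

sbml_fixture_path <- function() {
  system.file("extdata", "synthetic_three_species.xml", package = "jacinv")
}
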