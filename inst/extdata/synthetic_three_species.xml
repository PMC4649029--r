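<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic three-species test network (hand-written fixture, not a
     published model): boundary-fed chain Xext -> S1 <-> S2 -> S3 -> (out)
     with one Michaelis-Menten step modified by S3, a reversible mass-action
     step, a reaction-local parameter, and an e-notation constant. -->
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">
  <model id="synthetic_three_species">
    <listOfCompartments>
      <compartment id="cytosol" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="Xext" compartment="cytosol" initialConcentration="5" boundaryCondition="true"/>
      <species id="S1" compartment="cytosol" initialConcentration="1"/>
      <species id="S2" compartment="cytosol" initialConcentration="0.5"/>
      <species id="S3" compartment="cytosol" initialConcentration="0.2"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="vin" value="0.15"/>
      <parameter id="kf" value="1.2"/>
      <parameter id="kr" value="0.4"/>
      <parameter id="kout" value="0.9"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="import" reversible="false">
        <listOfReactants>
          <speciesReference species="Xext"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="S1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>vin</ci><ci>Xext</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="isomerase" reversible="true">
        <listOfReactants>
          <speciesReference species="S1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="S2"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><minus/>
              <apply><times/><ci>kf</ci><ci>S1</ci></apply>
              <apply><times/><ci>kr</ci><ci>S2</ci></apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="mm_step" reversible="false">
        <listOfReactants>
          <speciesReference species="S2"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="S3"/>
        </listOfProducts>
        <listOfModifiers>
          <modifierSpeciesReference species="S3"/>
        </listOfModifiers>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><divide/>
              <apply><times/><ci>Vmax</ci><ci>S2</ci></apply>
              <apply><plus/>
                <ci>Km</ci>
                <ci>S2</ci>
                <apply><times/><ci>Ki</ci><ci>S3</ci></apply>
              </apply>
            </apply>
          </math>
          <listOfParameters>
            <parameter id="Vmax" value="2.5"/>
            <parameter id="Km" value="0.3"/>
            <parameter id="Ki" value="1.5"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="export" reversible="false">
        <listOfReactants>
          <speciesReference species="S3"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/>
              <cn type="e-notation">9 <sep/> -1</cn>
              <ci>kout</ci>
              <ci>S3</ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
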