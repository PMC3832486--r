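<?xml version="1.0" encoding="UTF-8"?>
<!-- Hand-written minimal SBML Level 2 document: zero-order synthesis plus
     first-order degradation, equivalent to the immigration_death MDL
     fixture. -->
<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">
  <model id="immigration_death">
    <listOfCompartments>
      <compartment id="cell" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="mRNA" compartment="cell" initialAmount="50"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="ksyn" value="10"/>
      <parameter id="kd" value="0.2"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="Rsyn" reversible="false">
        <listOfProducts>
          <speciesReference species="mRNA" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <ci>ksyn</ci>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="Rdeg" reversible="false">
        <listOfReactants>
          <speciesReference species="mRNA" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>kd</ci><ci>mRNA</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
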