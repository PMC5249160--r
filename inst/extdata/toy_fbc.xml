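<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_fbc" fbc:strict="true">
    <listOfParameters>
      <parameter id="lb_free" value="-1000" constant="true"/>
      <parameter id="ub_free" value="1000" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_cap4" value="4" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="A" compartment="c" boundaryCondition="false" constant="false"/>
      <species id="B" compartment="c" boundaryCondition="false" constant="false"/>
      <species id="C" compartment="c" boundaryCondition="false" constant="false"/>
      <species id="A_ext" compartment="e" boundaryCondition="true" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fbc:lowerFluxBound="lb_free" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_ext" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="g1"/>
            <fbc:geneProductRef fbc:geneProduct="g2"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="B1" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_cap4">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="g3"/>
            <fbc:geneProductRef fbc:geneProduct="g4"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="GROWTH" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_free">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="g4" fbc:label="g4"/>
    </fbc:listOfGeneProducts>
  </model>
</sbml>
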