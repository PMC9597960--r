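<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="chain3" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="a" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="b" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_ex" value="-10" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="gp_G1" fbc:label="G1"/>
      <fbc:geneProduct fbc:id="gp_G2" fbc:label="G2"/>
      <fbc:geneProduct fbc:id="gp_G3" fbc:label="G3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_a" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_ex" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="a" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="CONV" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="a" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="b" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="gp_G1"/>
            <fbc:geneProductRef fbc:geneProduct="gp_G2"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="GROWTH" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="b" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="gp_G3"/>
        </fbc:geneProductAssociation>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
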