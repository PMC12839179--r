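# Sagittal-plane lower-limb muscle parameter table (one leg; the package
# mirrors it per side).  Values are literature-anchored Hill-type parameters
# in the tradition of generic full-body gait models (Delp/Arnold/Rajagopal
# families), rounded and grouped: `vasti` and `hamstrings` lump their
# respective heads.  Reference subject: mass 75.2 kg, height 1.70 m;
# f_max scales linearly with body mass, l_opt and tendon_slack with height.
# Moment arms [m] are low-order polynomials of the joint angle,
# r(theta) = r0 + r1 * theta, stored in the joint's positive-moment
# convention (ankle plantarflexion+, knee extension+, hip extension+), with
# angles dorsiflexion+/flexion+.  NA means the muscle does not span the
# joint.  fast_twitch_fraction values follow commonly used fiber-typing
# compilations (Johnson et al.-style).
name,f_max,l_opt,tendon_slack,v_max,pennation,fast_twitch_fraction,ankle_r0,ankle_r1,knee_r0,knee_r1,hip_r0,hip_r1
soleus,3600,0.050,0.250,10,0.44,0.20,0.050,-0.010,NA,NA,NA,NA
gastroc_med,1558,0.060,0.390,10,0.30,0.45,0.048,-0.010,-0.018,0,NA,NA
gastroc_lat,683,0.064,0.380,10,0.14,0.45,0.045,-0.010,-0.016,0,NA,NA
tib_ant,1200,0.068,0.240,10,0.09,0.25,-0.040,-0.005,NA,NA,NA,NA
vasti,5000,0.090,0.130,10,0.05,0.50,NA,NA,0.045,-0.010,NA,NA
rect_fem,1200,0.114,0.310,10,0.09,0.55,NA,NA,0.042,-0.010,-0.050,0
hamstrings,3000,0.100,0.330,10,0.00,0.45,NA,NA,-0.030,0,0.060,0
glut_max,2500,0.147,0.125,10,0.00,0.50,NA,NA,NA,NA,0.062,0
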