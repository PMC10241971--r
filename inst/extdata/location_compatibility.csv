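body_site,regions,wildcard
Skin tissue,,TRUE
Entire skin of abdomen,TORSO_FRONT;TORSO_SIDES,FALSE
Entire skin of chest,TORSO_FRONT;TORSO_SIDES,FALSE
Entire skin of back,TORSO_BACK;TORSO_SIDES,FALSE
Entire skin of cheek,HEAD_NECK_FRONT,FALSE
Entire skin of chin,HEAD_NECK_FRONT,FALSE
Entire skin of head,HEAD_NECK_FRONT;HEAD_NECK_BACK,FALSE
Entire skin of shoulder,RIGHT_ARM_LEFT_SIDE;LEFT_ARM_UP,FALSE
Entire skin of forearm,LEFT_ARM_FRONT;LEFT_ARM_BACK;RIGHT_ARM_FRONT;RIGHT_ARM_BACK,FALSE
Entire skin of upper arm,LEFT_ARM_UP;RIGHT_ARM_LEFT_SIDE,FALSE
Entire skin of upper extremity,LEFT_ARM_FRONT;LEFT_ARM_BACK;LEFT_ARM_UP;RIGHT_ARM_FRONT;RIGHT_ARM_BACK;RIGHT_ARM_LEFT_SIDE,FALSE
Entire skin of foot,LEFT_LEG_FRONT;LEFT_LEG_BACK;RIGHT_LEG_FRONT;RIGHT_LEG_BACK,FALSE
Entire skin of lower leg,LEFT_LEG_FRONT;LEFT_LEG_BACK;RIGHT_LEG_FRONT;RIGHT_LEG_BACK,FALSE
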